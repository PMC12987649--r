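#' Parameters of the synthetic L5-like morphology
#'
#' The package ships a deterministic template tree standing in for a
#' reconstructed layer 5 pyramidal tract neuron: a soma, a short axon, an
#' apical trunk rising to the nexus (the first major apical bifurcation)
#' where the tuft branches out in three orders, and a fan of basal
#' dendrites. Default branch lengths are chosen so the apical cable totals
#' 7440 um and the basal cable 4649 um, the values the synapse-density
#' budget is built on. `scale` shrinks every branch proportionally for
#' desk-scale simulations while leaving densities (and hence the local
#' synaptic physiology) untouched.
#'
#' @param scale Global multiplier on branch lengths (> 0).
#' @param seg_max Maximum compartment length in um (default 20).
#' @param length_jitter Standard deviation (fractional, log scale) of
#'   seedable branch-length jitter; 0 (default) gives the exact template.
#' @param soma_L,soma_diam Soma cylinder length/diameter, um.
#' @param axon_L,axon_diam Axon length/diameter, um.
#' @param trunk_L Apical trunk length, um.
#' @param trunk_diam Trunk diameter at soma and at nexus (length-2, tapered).
#' @param nexus_L,nexus_diam Nexus section geometry, um.
#' @param tuft_L Lengths of tuft branch orders 1..3 (2/4/8 branches), um.
#' @param tuft_diam Diameters of tuft branch orders 1..3, um.
#' @param n_basal Number of basal primary branches.
#' @param basal_L Lengths of basal orders 1..2, um (order 2 has `2*n_basal`
#'   branches).
#' @param basal_diam Diameters of basal orders 1..2, um.
#' @return A list of class `morph_params`.
#' @export
morphology_params <- function(scale = 1, seg_max = 20, length_jitter = 0,
                              soma_L = 25, soma_diam = 25,
                              axon_L = 60, axon_diam = 1.5,
                              trunk_L = 600, trunk_diam = c(4, 2.5),
                              nexus_L = 40, nexus_diam = 2.5,
                              tuft_L = c(500, 600, 425),
                              tuft_diam = c(1.5, 1.1, 0.9),
                              n_basal = 8,
                              basal_L = c(60, 260.5625),
                              basal_diam = c(1.6, 0.9)) {
  p <- as.list(environment())
  if (scale <= 0) stop("scale must be positive")
  if (seg_max <= 0) stop("seg_max must be positive")
  if (any(c(soma_L, soma_diam, axon_L, trunk_L, nexus_L, tuft_L, basal_L) <= 0)) {
    stop("all lengths must be positive")
  }
  structure(p, class = "morph_params")
}

# internal: split one branch into compartments no longer than seg_max
.segment_branch <- function(df, parent_id, L, diam, region, branch_id,
                            origin, direction, seg_max) {
  n <- max(1L, as.integer(ceiling(L / seg_max)))
  seg_L <- L / n
  ids <- nrow(df) + seq_len(n)
  if (length(diam) == 1) diam <- rep(diam, 2)
  d <- diam[1] + (diam[2] - diam[1]) * (seq_len(n) - 0.5) / n
  ends <- t(vapply(seq_len(n), function(i) origin + direction * seg_L * i,
                   numeric(3)))
  new <- data.frame(
    id = ids,
    parent = c(parent_id, ids[-n]),
    length = seg_L,
    diam = d,
    region = region,
    branch = branch_id,
    x = ends[, 1], y = ends[, 2], z = ends[, 3]
  )
  rbind(df, new)
}

#' Build the synthetic pyramidal-cell morphology
#'
#' Constructs the compartmentalised tree described by [morphology_params()]:
#' a rooted table of cylindrical compartments (each at most `seg_max` um
#' long) with region tags in \{soma, axon, basal, apical_trunk, nexus,
#' tuft\} and path distances from the soma. At the default settings the
#' apical cable totals 7440 um and the basal cable 4649 um.
#'
#' @param params A `morph_params` object.
#' @param seed Optional integer seed for branch-length jitter.
#' @return An object of class `morphology`: list with `df` (compartment
#'   table: id, parent, length, diam, region, branch, x, y, z, path_dist)
#'   and `params`. `path_dist` is measured to the compartment midpoint, with
#'   the soma at 0.
#' @examples
#' m <- build_synthetic_morphology()
#' cable_lengths(m)
#' @export
build_synthetic_morphology <- function(params = morphology_params(),
                                       seed = NULL) {
  if (!inherits(params, "morph_params")) stop("params must be morph_params")
  if (!is.null(seed)) set.seed(seed)
  p <- params
  jit <- function(L) {
    if (p$length_jitter > 0) L * exp(stats::rnorm(length(L), 0, p$length_jitter)) else L
  }
  s <- p$scale
  df <- data.frame(
    id = 1L, parent = -1L, length = p$soma_L, diam = p$soma_diam,
    region = "soma", branch = 0L, x = 0, y = 0, z = 0
  )
  branch_id <- 1L
  # axon, straight down
  df <- .segment_branch(df, 1L, p$axon_L, p$axon_diam, "axon", branch_id,
                        c(0, 0, 0), c(0, -1, 0), p$seg_max)
  # apical trunk, straight up, tapered
  branch_id <- branch_id + 1L
  trunk_L <- jit(p$trunk_L) * s
  df <- .segment_branch(df, 1L, trunk_L, p$trunk_diam, "apical_trunk",
                        branch_id, c(0, 0, 0), c(0, 1, 0), p$seg_max)
  trunk_tip <- nrow(df)
  trunk_origin <- c(0, trunk_L, 0)
  # nexus
  branch_id <- branch_id + 1L
  nexus_L <- jit(p$nexus_L) * s
  df <- .segment_branch(df, trunk_tip, nexus_L, p$nexus_diam, "nexus",
                        branch_id, trunk_origin, c(0, 1, 0), p$seg_max)
  nexus_tip <- nrow(df)
  nexus_origin <- trunk_origin + c(0, nexus_L, 0)
  # tuft: binary tree of three orders rooted at the nexus
  grow <- function(df, parents, origins, order, base_angle) {
    if (order > length(p$tuft_L)) return(df)
    out_parents <- integer(0)
    out_origins <- list()
    k <- 0L
    for (i in seq_along(parents)) {
      for (side in c(-1, 1)) {
        branch_id <<- branch_id + 1L
        ang <- base_angle * side / order
        dir <- c(sin(ang), cos(ang), 0.15 * side * order)
        dir <- dir / sqrt(sum(dir^2))
        L <- jit(p$tuft_L[order]) * s
        df <- .segment_branch(df, parents[i], L, p$tuft_diam[order], "tuft",
                              branch_id, origins[[i]], dir, p$seg_max)
        k <- k + 1L
        out_parents[k] <- nrow(df)
        out_origins[[k]] <- origins[[i]] + dir * L
      }
    }
    grow(df, out_parents, out_origins, order + 1L, base_angle)
  }
  df <- grow(df, nexus_tip, list(nexus_origin), 1L, 0.9)
  # basal fan: n_basal primaries, each bifurcating once
  for (b in seq_len(p$n_basal)) {
    ang <- pi * (b - 0.5) / p$n_basal
    dir1 <- c(cos(ang), -0.6, sin(ang))
    dir1 <- dir1 / sqrt(sum(dir1^2))
    branch_id <- branch_id + 1L
    L1 <- jit(p$basal_L[1]) * s
    df <- .segment_branch(df, 1L, L1, p$basal_diam[1], "basal", branch_id,
                          c(0, 0, 0), dir1, p$seg_max)
    prim_tip <- nrow(df)
    prim_end <- dir1 * L1
    for (side in c(-1, 1)) {
      branch_id <- branch_id + 1L
      dir2 <- dir1 + side * c(-dir1[3], 0, dir1[1]) * 0.5
      dir2 <- dir2 / sqrt(sum(dir2^2))
      df <- .segment_branch(df, prim_tip, jit(p$basal_L[2]) * s,
                            p$basal_diam[2], "basal", branch_id,
                            prim_end, dir2, p$seg_max)
    }
  }
  rownames(df) <- NULL
  df$path_dist <- .path_distances(df)
  structure(list(df = df, params = params), class = "morphology")
}

# internal: path distance (um) from the soma surface to each compartment
# midpoint; the soma itself is at 0 and its length does not count.
.path_distances <- function(df) {
  pd_end <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$parent[i] < 0 || df$region[i] == "soma") {
      pd_end[i] <- 0
    } else {
      par <- df$parent[i]
      base <- if (df$region[par] == "soma") 0 else pd_end[par]
      pd_end[i] <- base + df$length[i]
    }
  }
  ifelse(df$region == "soma", 0, pd_end - df$length / 2)
}

#' @export
print.morphology <- function(x, ...) {
  len <- cable_lengths(x)
  cat(sprintf(
    "<morphology> %d compartments | apical %.0f um, basal %.0f um\n",
    nrow(x$df), len[["apical"]], len[["basal"]]
  ))
  invisible(x)
}

#' Total cable length per region and per dendrite class
#'
#' @param morph A `morphology`.
#' @return Named numeric vector of cable lengths (um) for each region tag
#'   plus the aggregates `apical` (trunk + nexus + tuft) and `basal`.
#' @export
cable_lengths <- function(morph) {
  stopifnot(inherits(morph, "morphology"))
  df <- morph$df
  by_region <- tapply(df$length, df$region, sum)
  out <- c(as.vector(by_region), sum(by_region[c("apical_trunk", "nexus", "tuft")],
                                     na.rm = TRUE))
  names(out) <- c(names(by_region), "apical")
  out["basal"] <- if ("basal" %in% names(by_region)) by_region[["basal"]] else 0
  out
}

#' Compartment ids belonging to the dendritic membrane
#' @param morph A `morphology`.
#' @param class `"apical"`, `"basal"`, or `"all"` dendritic compartments.
#' @return Integer compartment ids.
#' @export
dendritic_ids <- function(morph, class = c("all", "apical", "basal")) {
  class <- match.arg(class)
  df <- morph$df
  keep <- switch(class,
    all = df$region %in% c("basal", "apical_trunk", "nexus", "tuft"),
    apical = df$region %in% c("apical_trunk", "nexus", "tuft"),
    basal = df$region == "basal"
  )
  df$id[keep]
}

#' Write / read a morphology in SWC format
#'
#' Standard 7-column SWC (index, type, x, y, z, radius, parent) with one
#' point per compartment distal end and type codes 1 soma / 2 axon /
#' 3 basal / 4 apical. The finer region tags (apical_trunk / nexus / tuft)
#' are not expressible in SWC types, so they are written to a sidecar table
#' `<path>.regions.tsv` which `read_swc` picks up when present.
#'
#' @param morph A `morphology`.
#' @param path Output file path.
#' @return `write_swc` returns `path` invisibly; `read_swc` returns a
#'   `morphology`.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "morphology"))
  df <- morph$df
  type <- c(soma = 1L, axon = 2L, basal = 3L, apical_trunk = 4L,
            nexus = 4L, tuft = 4L)[df$region]
  swc <- data.frame(
    index = df$id, type = type, x = df$x, y = df$y, z = df$z,
    radius = df$diam / 2, parent = df$parent
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export; 1 soma / 2 axon / 3 basal / 4 apical", con)
  utils::write.table(format(swc, digits = 12, trim = TRUE), con,
                     sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(id = df$id, region = df$region),
                     paste0(path, ".regions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  swc <- utils::read.table(path, comment.char = "#",
                           col.names = c("index", "type", "x", "y", "z",
                                         "radius", "parent"))
  region <- c("soma", "axon", "basal", "apical_trunk")[swc$type]
  sidecar <- paste0(path, ".regions.tsv")
  if (file.exists(sidecar)) {
    reg <- utils::read.table(sidecar, header = TRUE, sep = "\t")
    region[match(reg$id, swc$index)] <- reg$region
  }
  L <- numeric(nrow(swc))
  for (i in seq_len(nrow(swc))) {
    if (swc$parent[i] < 0) {
      L[i] <- 2 * swc$radius[i] # root soma point: sphere-equivalent cylinder
    } else {
      par <- match(swc$parent[i], swc$index)
      pxyz <- if (swc$type[par] == 1 && swc$parent[par] < 0) {
        c(0, 0, 0) # children of the soma sprout from its centre
      } else {
        unlist(swc[par, c("x", "y", "z")])
      }
      L[i] <- sqrt(sum((unlist(swc[i, c("x", "y", "z")]) - pxyz)^2))
    }
  }
  df <- data.frame(
    id = swc$index, parent = swc$parent, length = L, diam = 2 * swc$radius,
    region = region, branch = NA_integer_,
    x = swc$x, y = swc$y, z = swc$z
  )
  df$path_dist <- .path_distances(df)
  structure(list(df = df, params = NULL), class = "morphology")
}
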