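# Synapse placement on the morphology.
#
# Excitatory contacts are organised hierarchically: each presynaptic node
# makes 2-8 contacts clustered within 5-10 um on a single branch, and the
# clusters belonging to one functional group (100 nodes) fall within a
# 100 um path-distance span. Inhibitory contacts are placed uniformly by
# cable length plus a fixed somatic contingent, and tagged perisomatic
# (path distance <= 100 um) or distal.

# internal: per-branch compartment bookkeeping for positioning along cable
.branch_index <- function(morph) {
  df <- morph$df
  dend <- df[df$region %in% c("basal", "apical_trunk", "nexus", "tuft"), ]
  split(dend[order(dend$id), c("id", "length", "path_dist", "region")],
        dend$branch[order(dend$id)])
}

# internal: convert an offset (um from branch start) into (comp, pos)
.locate_on_branch <- function(branch_df, offset) {
  ends <- cumsum(branch_df$length)
  i <- findInterval(offset, c(0, ends), rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(branch_df))
  start <- c(0, ends)[i]
  pos <- (offset - start) / branch_df$length[i]
  list(comp = branch_df$id[i], pos = min(max(pos, 0), 1))
}

#' Place excitatory synapses with functional-group clustering
#'
#' Distributes `round(density * cable length)` AMPA/NMDA synapses over each
#' dendritic subtree (apical and basal). Contacts are created node by node:
#' every presynaptic node makes `divergence` contacts (uniform on 2..8) in a
#' 5-10 um cluster on one branch, shares one release probability (uniform on
#' 0.16-0.9), and consecutive blocks of `group_size` nodes form functional
#' groups whose clusters sit within a 100 um path-distance span.
#'
#' @param morph A `morphology`.
#' @param density Contacts per um of cable (default 2.16).
#' @param seed Optional integer seed.
#' @param divergence Integer range of contacts per node (default 2:8).
#' @param p_range Release-probability range (default `c(0.16, 0.9)`).
#' @param group_size Nodes per functional group (default 100; clipped to the
#'   available node count for small morphologies).
#' @param cluster_span Within-node cluster span, um (default `c(5, 10)`).
#' @param group_span Path-distance span of a functional group, um.
#' @return Data frame with one row per synapse: `synapse_id`, `comp`, `pos`,
#'   `class`, `subtree`, `zone`, `node_id`, `group_id`, `p_release`, `stp`,
#'   `g_max_uS` (NA until [draw_weights()]).
#' @export
place_excitatory_synapses <- function(morph, density = 2.16, seed = NULL,
                                      divergence = 2:8,
                                      p_range = c(0.16, 0.9),
                                      group_size = 100,
                                      cluster_span = c(5, 10),
                                      group_span = 100) {
  stopifnot(inherits(morph, "morphology"))
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  if (!is.null(seed)) set.seed(seed)
  lens <- cable_lengths(morph)
  branches <- .branch_index(morph)
  if (!length(branches)) {
    return(.empty_synapse_table())
  }
  branch_region <- vapply(branches, function(b) b$region[1], character(1))
  branch_sub <- ifelse(branch_region == "basal", "basal", "apical")
  branch_len <- vapply(branches, function(b) sum(b$length), numeric(1))
  branch_pd <- vapply(branches, function(b) b$path_dist[1], numeric(1))

  out <- list()
  node_id <- 0L
  for (sub in c("apical", "basal")) {
    target <- round(density * lens[[sub]])
    if (target < 1) next
    cand <- which(branch_sub == sub & branch_len >= cluster_span[2])
    if (!length(cand)) cand <- which(branch_sub == sub)
    placed <- 0L
    rows <- list()
    group_anchor <- NA_real_
    nodes_in_group <- 0L
    gs <- group_size
    group_id <- 0L
    while (placed < target) {
      if (nodes_in_group == 0L) {
        group_id <- group_id + 1L
        anchor_b <- sample(cand, 1)
        group_anchor <- branch_pd[anchor_b]
      }
      node_id <- node_id + 1L
      k <- min(sample(divergence, 1), target - placed)
      p <- stats::runif(1, p_range[1], p_range[2])
      near <- cand[abs(branch_pd[cand] - group_anchor) <= group_span]
      if (!length(near)) near <- cand
      b <- if (length(near) == 1) near else sample(near, 1)
      bdf <- branches[[b]]
      span <- stats::runif(1, cluster_span[1], cluster_span[2])
      blen <- branch_len[b]
      start <- stats::runif(1, 0, max(blen - span, 0))
      offs <- start + sort(stats::runif(k, 0, min(span, blen)))
      loc <- lapply(offs, .locate_on_branch, branch_df = bdf)
      rows[[length(rows) + 1L]] <- data.frame(
        comp = vapply(loc, `[[`, integer(1), "comp"),
        pos = vapply(loc, `[[`, numeric(1), "pos"),
        subtree = sub, node_id = node_id, group_id = group_id,
        p_release = p
      )
      placed <- placed + k
      nodes_in_group <- (nodes_in_group + 1L) %% gs
    }
    out[[sub]] <- do.call(rbind, rows)
  }
  specs <- do.call(rbind, out)
  if (is.null(specs)) {
    return(.empty_synapse_table())
  }
  pd <- morph$df$path_dist[match(specs$comp, morph$df$id)]
  data.frame(
    synapse_id = seq_len(nrow(specs)),
    comp = specs$comp, pos = specs$pos,
    class = "exc", subtree = specs$subtree,
    zone = ifelse(pd <= 100, "perisomatic", "distal"),
    node_id = specs$node_id, group_id = specs$group_id,
    p_release = specs$p_release, stp = "excitatory",
    g_max_uS = NA_real_
  )
}

.empty_synapse_table <- function() {
  data.frame(
    synapse_id = integer(), comp = integer(), pos = numeric(),
    class = character(), subtree = character(), zone = character(),
    node_id = integer(), group_id = integer(), p_release = numeric(),
    stp = character(), g_max_uS = numeric()
  )
}

# internal: rounded-normal divergence draws, clipped to >= 1
.draw_divergence <- function(n, mean, sd) {
  pmax(1L, as.integer(round(stats::rnorm(n, mean, sd))))
}

#' Place inhibitory synapses (somatic contingent plus dendritic density)
#'
#' `n_somatic` GABA_A contacts go on the soma; the dendritic membrane
#' receives `round(density * cable length)` contacts per subtree placed
#' uniformly by cable length. Contacts are tagged `perisomatic` when within
#' 100 um path distance of the soma (somatic contacts included) and `distal`
#' otherwise, and assigned to presynaptic nodes with divergence drawn from a
#' rounded normal (clipped at 1): perisomatic 2.8 +/- 1.9, basal 2.7 +/-
#' 1.6, apical 12 +/- 3. Release probabilities follow the same groups
#' (0.88 +/- 0.05, 0.72 +/- 0.10, 0.30 +/- 0.08, truncated to (0, 1]).
#'
#' @param morph A `morphology`.
#' @param density Contacts per um of dendritic cable (default 0.22).
#' @param n_somatic Somatic contact count (default 150).
#' @param seed Optional integer seed.
#' @param perisomatic_um Path-distance cutoff for the perisomatic zone, um.
#' @return Synapse table as in [place_excitatory_synapses()], with `stp` set
#'   to `"perisomatic_inh"` or `"dendritic_inh"` by zone.
#' @export
place_inhibitory_synapses <- function(morph, density = 0.22, n_somatic = 150,
                                      seed = NULL, perisomatic_um = 100) {
  stopifnot(inherits(morph, "morphology"))
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  if (!is.null(seed)) set.seed(seed)
  df <- morph$df
  lens <- cable_lengths(morph)
  soma_ids <- df$id[df$region == "soma"]
  rows <- list()
  if (n_somatic > 0) {
    rows$soma <- data.frame(
      comp = sample(soma_ids, n_somatic, replace = TRUE),
      pos = stats::runif(n_somatic), subtree = "soma"
    )
  }
  for (sub in c("apical", "basal")) {
    ids <- dendritic_ids(morph, sub)
    target <- round(density * lens[[sub]])
    if (target < 1 || !length(ids)) next
    w <- df$length[match(ids, df$id)]
    rows[[sub]] <- data.frame(
      comp = sample(ids, target, replace = TRUE, prob = w),
      pos = stats::runif(target), subtree = sub
    )
  }
  specs <- do.call(rbind, rows)
  pd <- df$path_dist[match(specs$comp, df$id)]
  zone <- ifelse(specs$subtree == "soma" | pd <= perisomatic_um,
                 "perisomatic", "distal")
  # three connection classes with distinct divergence / release statistics
  cls <- ifelse(zone == "perisomatic", "peri",
                ifelse(specs$subtree == "basal", "basal", "apical"))
  div_par <- list(peri = c(2.8, 1.9), basal = c(2.7, 1.6), apical = c(12, 3))
  p_par <- list(peri = c(0.88, 0.05), basal = c(0.72, 0.10),
                apical = c(0.30, 0.08))
  node_id <- integer(nrow(specs))
  p_rel <- numeric(nrow(specs))
  next_node <- 0L
  for (cl in c("peri", "basal", "apical")) {
    idx <- which(cls == cl)
    if (!length(idx)) next
    filled <- 0L
    while (filled < length(idx)) {
      next_node <- next_node + 1L
      k <- min(.draw_divergence(1, div_par[[cl]][1], div_par[[cl]][2]),
               length(idx) - filled)
      sel <- idx[(filled + 1L):(filled + k)]
      node_id[sel] <- next_node
      p <- stats::rnorm(1, p_par[[cl]][1], p_par[[cl]][2])
      p_rel[sel] <- min(max(p, 0.01), 1)
      filled <- filled + k
    }
  }
  data.frame(
    synapse_id = seq_len(nrow(specs)),
    comp = specs$comp, pos = specs$pos,
    class = "inh", subtree = specs$subtree, zone = zone,
    node_id = node_id, group_id = NA_integer_,
    p_release = p_rel,
    stp = ifelse(zone == "perisomatic", "perisomatic_inh", "dendritic_inh"),
    g_max_uS = NA_real_
  )
}

#' Place a patch of clustered excitatory synapses
#'
#' Adds a concentrated excitatory input patch: `n_synapses` contacts spread
#' over `span_um` of cable (default 187 over 140 um, i.e. 1.3 contacts/um)
#' either at the nexus (the 140 um of apical cable starting at the
#' trunk-tuft bifurcation) or on basal dendrites adjoining the soma.
#'
#' @param morph A `morphology`.
#' @param where `"nexus"` or `"basal"`.
#' @param n_synapses Number of contacts (default 187).
#' @param span_um Cable span receiving the patch, um (default 140).
#' @param seed Optional integer seed.
#' @return List with `specs` (synapse table rows, `class = "exc"`, `zone`
#'   from path distance, no node assignment) and `density` (contacts/um).
#' @export
place_clustered_synapses <- function(morph, where = c("nexus", "basal"),
                                     n_synapses = 187, span_um = 140,
                                     seed = NULL) {
  where <- match.arg(where)
  stopifnot(inherits(morph, "morphology"))
  if (!is.null(seed)) set.seed(seed)
  df <- morph$df
  if (where == "nexus") {
    # walk distally from the start of the nexus section
    nex <- df[df$region %in% c("nexus", "tuft"), ]
    nex <- nex[order(nex$path_dist), ]
    cum <- cumsum(nex$length)
    sel <- nex[cum <= span_um + max(nex$length), ]
  } else {
    bas <- df[df$region == "basal", ]
    bas <- bas[order(bas$path_dist), ]
    cum <- cumsum(bas$length)
    sel <- bas[cum <= span_um + max(bas$length), ]
  }
  avail <- sum(sel$length)
  if (avail < span_um * 0.5) {
    stop("morphology too small to host the requested cluster span")
  }
  comp <- sample(sel$id, n_synapses, replace = TRUE, prob = sel$length)
  pd <- df$path_dist[match(comp, df$id)]
  specs <- data.frame(
    synapse_id = seq_len(n_synapses),
    comp = comp, pos = stats::runif(n_synapses),
    class = "exc", subtree = if (where == "nexus") "apical" else "basal",
    zone = ifelse(pd <= 100, "perisomatic", "distal"),
    node_id = NA_integer_, group_id = NA_integer_,
    p_release = stats::runif(n_synapses, 0.16, 0.9), stp = "excitatory",
    g_max_uS = NA_real_
  )
  list(specs = specs, density = n_synapses / span_um, span_um = span_um)
}

#' Write / read a synapse table as delimited text
#'
#' Columns: synapse_id, compartment_id, pos, class, g_max_uS, p_release,
#' node_id, zone (plus subtree, group_id, stp kept for reproducibility).
#'
#' @param specs Synapse table.
#' @param path File path.
#' @export
write_synapses <- function(specs, path) {
  utils::write.table(specs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_synapses
#' @export
read_synapses <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
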