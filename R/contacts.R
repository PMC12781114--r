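#' Residue contacts of a single frame
#'
#' Two residues are in contact when ANY pair of their heavy (non-hydrogen)
#' atoms lies within `cutoff` Angstrom (inclusive) and the residues are
#' separated by at least `min_separation` positions in sequence (pairs on
#' different chains always pass the separation filter). The kernel bins
#' atoms into a cell list, so cost grows linearly with atom count.
#'
#' @param frame N x 3 coordinate matrix for the full topology.
#' @param topology the [Structure] describing the atoms.
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @param min_separation minimum sequence separation (default 3, i.e. i to
#'   i+n with n >= 3).
#' @return integer matrix with columns `i`, `j` (1-based indices into
#'   [residue_ids()] order, `i < j`), one row per contacting pair.
#' @export
frame_contacts <- function(frame, topology, cutoff = 4.5,
                           min_separation = 3L) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  frame <- as.matrix(frame)
  if (nrow(frame) != n_atoms(topology))
    stop("frame atom count does not match topology")
  heavy <- toupper(topology$atoms$element) != "H"
  if (!any(heavy)) stop("empty heavy-atom set")
  rmap <- atom_residue_index(topology)
  rlab <- residue_ids(topology)
  first <- match(seq_along(rlab), rmap)
  resseq <- topology$atoms$resid[first]
  reschain <- as.integer(factor(topology$atoms$chain[first]))
  pairs <- residue_contacts_cell(frame[heavy, , drop = FALSE],
                                 as.integer(rmap[heavy]),
                                 as.integer(resseq), reschain,
                                 cutoff, as.integer(min_separation))
  colnames(pairs) <- c("i", "j")
  pairs
}

#' Contact probabilities over a trajectory
#'
#' `value[i, j]` is the fraction of frames in which residues i and j are in
#' contact per [frame_contacts()].
#'
#' @param trajectory a [Trajectory].
#' @inheritParams frame_contacts
#' @return a `ContactProbabilityMatrix`: symmetric `values` matrix in
#'   `[0, 1]` with residue labels, plus `n_frames_used`,
#'   `min_sequence_separation` and `cutoff`.
#' @export
contact_probabilities <- function(trajectory, cutoff = 4.5,
                                  min_separation = 3L) {
  top <- trajectory$topology
  rlab <- residue_ids(top)
  nr <- length(rlab)
  counts <- matrix(0, nr, nr, dimnames = list(rlab, rlab))
  nf <- n_frames(trajectory)
  for (f in seq_len(nf)) {
    p <- frame_contacts(frame_coords(trajectory, f), top, cutoff,
                        min_separation)
    if (nrow(p)) {
      counts[p] <- counts[p] + 1
    }
  }
  values <- counts / nf
  values <- values + t(values)
  structure(list(values = values, n_frames_used = nf,
                 min_sequence_separation = as.integer(min_separation),
                 cutoff = cutoff),
            class = "ContactProbabilityMatrix")
}

#' @export
print.ContactProbabilityMatrix <- function(x, ...) {
  cat("ContactProbabilityMatrix:", nrow(x$values), "residues,",
      sum(x$values[upper.tri(x$values)] > 0), "pairs ever in contact,",
      x$n_frames_used, "frames\n")
  invisible(x)
}

#' Contact-probability difference network (dCNA edge weights)
#'
#' `df[i, j] = P_b(i, j) - P_a(i, j)`; positive df means the contact FORMS
#' going from system A to system B, negative means it BREAKS.
#'
#' @param p_a,p_b `ContactProbabilityMatrix` objects over the same residue
#'   universe and with the same minimum sequence separation (conventionally
#'   A = wild type, B = mutant).
#' @param labels character(2) system labels `(A, B)`.
#' @return a `DifferenceNetwork`: symmetric `df` matrix in `[-1, 1]` and
#'   `system_labels`.
#' @export
difference_network <- function(p_a, p_b, labels = c("A", "B")) {
  if (!identical(dimnames(p_a$values), dimnames(p_b$values)))
    stop("residue universes differ between the two probability matrices")
  if (p_a$min_sequence_separation != p_b$min_sequence_separation)
    stop("minimum sequence separation differs between inputs")
  structure(list(df = p_b$values - p_a$values,
                 system_labels = labels),
            class = "DifferenceNetwork")
}

#' @export
print.DifferenceNetwork <- function(x, ...) {
  ut <- x$df[upper.tri(x$df)]
  cat("DifferenceNetwork ", x$system_labels[1], " -> ", x$system_labels[2],
      ": ", sum(ut > 0), " formed, ", sum(ut < 0), " broken pairs\n",
      sep = "")
  invisible(x)
}

#' Consensus residue communities from stable contacts
#'
#' Per trajectory block, a graph is built over residues with an edge for
#' every pair whose contact probability is at least `stable_threshold`
#' (edge weight = probability) and partitioned by greedy modularity
#' maximisation. The consensus partition is the majority co-classification:
#' residues end up in one consensus community when they share a block-level
#' community in more than half of the blocks. Residues with no stable
#' contact in any block become singleton communities and are flagged.
#'
#' @param probability_matrices list of `ContactProbabilityMatrix` objects,
#'   one per trajectory block (equal-length blocks recommended).
#' @param stable_threshold occupancy above which a contact counts as stable
#'   (default 0.7).
#' @return a `CommunityPartition`: integer `labels` (residue -> community id,
#'   ids contiguous from 1 in order of first residue), `n_communities`,
#'   per-residue consensus `stability` in `[0, 1]`, and `isolated` flags.
#' @export
consensus_communities <- function(probability_matrices,
                                  stable_threshold = 0.7) {
  if (inherits(probability_matrices, "ContactProbabilityMatrix"))
    probability_matrices <- list(probability_matrices)
  if (!length(probability_matrices)) stop("no probability matrices supplied")
  if (stable_threshold <= 0 || stable_threshold > 1)
    stop("stable_threshold must lie in (0, 1]")
  rlab <- rownames(probability_matrices[[1]]$values)
  nr <- length(rlab)
  for (p in probability_matrices)
    if (!identical(rownames(p$values), rlab))
      stop("probability matrices disagree on residue universe")
  block_labels <- lapply(probability_matrices, function(p) {
    adj <- p$values
    adj[adj < stable_threshold] <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    memb <- rep(NA_integer_, nr)
    deg <- igraph::degree(g)
    if (any(deg > 0)) {
      sub <- igraph::induced_subgraph(g, which(deg > 0))
      cl <- igraph::cluster_fast_greedy(sub)
      # pick the dendrogram cut of maximal modularity; on ties prefer the
      # coarsest partition (a clique then stays one community)
      best <- NULL
      best_q <- -Inf
      for (k in seq_len(igraph::vcount(sub))) {
        # cut_at warns for cuts below the number of components; those
        # probes are expected and simply skipped
        mb <- tryCatch(suppressWarnings(igraph::cut_at(cl, no = k)),
                       error = function(e) NULL)
        if (is.null(mb)) next
        q <- igraph::modularity(sub, mb, weights = igraph::E(sub)$weight)
        if (q > best_q + 1e-12) {
          best_q <- q
          best <- mb
        }
      }
      memb[deg > 0] <- best
    }
    memb
  })
  # co-classification fraction across blocks
  nb <- length(block_labels)
  co <- matrix(0, nr, nr)
  for (bl in block_labels) {
    same <- outer(bl, bl, function(a, b) !is.na(a) & !is.na(b) & a == b)
    co <- co + same
  }
  co <- co / nb
  g <- igraph::graph_from_adjacency_matrix(co > 0.5, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # contiguous ids ordered by first residue appearance
  labels <- match(comp, unique(comp))
  isolated <- vapply(seq_len(nr), function(r)
    all(vapply(block_labels, function(bl) is.na(bl[r]), logical(1))),
    logical(1))
  stability <- vapply(seq_len(nr), function(r) {
    peers <- setdiff(which(labels == labels[r]), r)
    if (!length(peers)) return(1)
    mean(vapply(block_labels, function(bl) {
      if (is.na(bl[r])) return(0)
      mean(!is.na(bl[peers]) & bl[peers] == bl[r])
    }, numeric(1)))
  }, numeric(1))
  names(labels) <- rlab
  structure(list(labels = labels, n_communities = max(labels),
                 stability = stats::setNames(stability, rlab),
                 isolated = stats::setNames(isolated, rlab),
                 stable_threshold = stable_threshold,
                 n_blocks = nb),
            class = "CommunityPartition")
}

#' @export
print.CommunityPartition <- function(x, ...) {
  cat("CommunityPartition:", x$n_communities, "consensus communities over",
      length(x$labels), "residues (", sum(x$isolated), "isolated );",
      sprintf("mean stability %.2f\n", mean(x$stability)))
  invisible(x)
}

#' Net contact changes between communities
#'
#' Aggregates a difference network over a community partition: the edge
#' between two communities is the SUM of signed pair df values across their
#' interface, and the diagonal holds the intra-community sums (each
#' unordered residue pair counted once).
#'
#' @param diff a `DifferenceNetwork`.
#' @param partition a `CommunityPartition` covering the same residues.
#' @return a `CommunityDifferenceGraph`: `nodes` data.frame (community,
#'   n_residues) and symmetric `net_df` matrix (diagonal = intra sums).
#' @export
community_difference <- function(diff, partition) {
  rlab <- rownames(diff$df)
  if (!all(rlab %in% names(partition$labels)))
    stop("partition does not label every residue in the difference network")
  lab <- partition$labels[rlab]
  nc <- partition$n_communities
  M <- matrix(0, nc, nc)
  # sum once per unordered residue pair
  ut <- which(upper.tri(diff$df), arr.ind = TRUE)
  vals <- diff$df[ut]
  nz <- vals != 0
  for (k in which(nz)) {
    a <- lab[ut[k, 1]]; b <- lab[ut[k, 2]]
    if (a == b) {
      M[a, a] <- M[a, a] + vals[k]
    } else {
      M[a, b] <- M[a, b] + vals[k]
      M[b, a] <- M[b, a] + vals[k]
    }
  }
  nodes <- data.frame(community = seq_len(nc),
                      n_residues = as.integer(table(factor(lab,
                                                           levels = seq_len(nc)))))
  structure(list(nodes = nodes, net_df = M,
                 system_labels = diff$system_labels),
            class = "CommunityDifferenceGraph")
}

#' @export
print.CommunityDifferenceGraph <- function(x, ...) {
  off <- x$net_df[upper.tri(x$net_df)]
  cat("CommunityDifferenceGraph:", nrow(x$nodes), "communities;",
      "largest interface |net df| =", sprintf("%.2f\n", max(abs(off), 0)))
  invisible(x)
}

#' Residue pairs with large contact-probability changes
#'
#' @param diff a `DifferenceNetwork`.
#' @param threshold minimum `|df|` to keep (default 0.5, inclusive).
#' @return data.frame (res_i, res_j, df) sorted by decreasing `|df|`, ties
#'   by pair index.
#' @export
significant_edges <- function(diff, threshold = 0.5) {
  if (threshold < 0) stop("threshold must be >= 0")
  rlab <- rownames(diff$df)
  ut <- which(upper.tri(diff$df), arr.ind = TRUE)
  vals <- diff$df[ut]
  keep <- which(abs(vals) >= threshold & vals != 0)
  ord <- keep[order(-abs(vals[keep]), ut[keep, 1], ut[keep, 2])]
  data.frame(res_i = rlab[ut[ord, 1]], res_j = rlab[ut[ord, 2]],
             df = vals[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a community partition as a pseudo-PDB with ids in the B-factor
#'
#' One CA record per residue; the community id goes into the B-factor
#' column so molecular viewers can colour by community.
#'
#' @param partition a `CommunityPartition`.
#' @param topology the [Structure] it was derived from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_communities_pdb <- function(partition, topology, path) {
  rmap <- atom_residue_index(topology)
  is_ca <- topology$atoms$name == "CA"
  idx <- which(is_ca)[!duplicated(rmap[is_ca])]
  a <- topology$atoms[idx, , drop = FALSE]
  bio3d::write.pdb(file = path,
                   xyz = flatten_coords(topology$coords[idx, , drop = FALSE]),
                   type = rep("ATOM", length(idx)), resno = a$resid,
                   resid = a$resname, eleno = a$eleno, elety = a$name,
                   chain = a$chain, elesy = a$element,
                   b = as.numeric(partition$labels[rmap[idx]]))
  invisible(path)
}
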