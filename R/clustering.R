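# Model-free agglomerative clustering built on the assignment solver
# ("Hungarian clustering"). Each level pairs current clusters with their most
# compatible distinct counterparts -- via a max-weight assignment on the
# average-linkage similarity matrix (self-pairing forbidden) augmented with
# all mutual-nearest-neighbour pairs -- and a proposed merge goes through
# only if it passes the validation gates below. Accepted edges are unioned
# transitively within a level; the process stops when no edge is accepted,
# so the number of clusters is an emergent property of the data. The whole
# procedure is deterministic.
#
# Validation gates for an edge (c, d):
#  (a) vicinity: the number of other clusters strictly more similar to c
#      than d (and vice versa) must stay below `t_all` (default ln n).
#  (b) homogeneity (active once both endpoints reach `size_gate` members):
#      the cross-cluster mean similarity must not fall more than `z_merge`
#      standard errors below the less homogeneous endpoint's within mean
#      (per-pair variance pooled over current within-cluster residuals).
#      A much smaller endpoint (splinter) is rescued when its similarity to
#      the large cluster sits more than `absorb_frac` of the way from the
#      background (best other sizeable cluster) up to the large cluster's
#      within level -- stragglers of a stratum are atypical members, so the
#      plain z-gate would strand them.
# A final absorption pass applies the same rescue rule to leftover clusters
# below `size_gate`.

.cluster_labels <- function(clusters) {
  if (inherits(clusters, "cluster_assignment")) clusters$labels
  else as.integer(as.factor(clusters))
}

.hc_level_stats <- function(sc, members) {
  n <- nrow(sc)
  m <- length(members)
  sizes <- lengths(members)
  Z <- matrix(0, n, m)
  for (k in seq_len(m)) Z[members[[k]], k] <- 1
  G <- crossprod(Z, sc %*% Z)
  cross_mean <- G / tcrossprod(sizes)
  within_mean <- ifelse(sizes >= 2, (diag(G) - sizes) / (sizes * (sizes - 1)), NA_real_)
  ss <- 0; dfree <- 0
  for (k in which(sizes >= 3)) {
    v <- sc[members[[k]], members[[k]]][upper.tri(diag(sizes[k]))]
    ss <- ss + sum((v - mean(v))^2)
    dfree <- dfree + length(v) - 1
  }
  v_pool <- if (dfree > 0) ss / dfree else stats::var(sc[upper.tri(sc)])
  list(m = m, sizes = sizes, cross = cross_mean, within = within_mean,
       v = max(v_pool, 0))
}

.hc_edge_ok <- function(st, c1, c2, z_merge, size_gate, absorb_frac, splinter_ratio) {
  if (min(st$sizes[c1], st$sizes[c2]) < size_gate) return(TRUE)
  w_ref <- suppressWarnings(min(st$within[c(c1, c2)], na.rm = TRUE))
  if (!is.finite(w_ref)) return(TRUE)
  iw <- c(c1, c2)[which.min(st$within[c(c1, c2)])]
  n_within <- max(1, st$sizes[iw] * (st$sizes[iw] - 1) / 2)
  se <- sqrt(st$v * (1 / (st$sizes[c1] * st$sizes[c2]) + 1 / n_within))
  s_cd <- st$cross[c1, c2]
  if (s_cd >= w_ref - z_merge * se) return(TRUE)
  if (min(st$sizes[c1], st$sizes[c2]) <= splinter_ratio * max(st$sizes[c1], st$sizes[c2])) {
    small <- if (st$sizes[c1] < st$sizes[c2]) c1 else c2
    bigc <- if (small == c1) c2 else c1
    others <- setdiff(which(st$sizes >= max(3, size_gate / 2)), c(c1, c2))
    if (length(others) > 0) {
      b <- max(st$cross[small, others])
      w_big <- st$within[bigc]
      if (is.finite(w_big) && w_big - b > 0) {
        return((s_cd - b) / (w_big - b) > absorb_frac)
      }
    }
  }
  FALSE
}

#' Agglomerative Hungarian clustering of a similarity matrix
#'
#' Hierarchical agglomeration in which every level solves an assignment
#' pairing the current clusters with their most similar distinct
#' counterparts; a pairing merges only if it passes a vicinity criterion and
#' a homogeneity criterion (details in the source header of this module).
#' The cluster count is found as part of the process, not preset.
#'
#' @param sim a `similarity_matrix` (or plain symmetric score matrix).
#' @param t_all vicinity threshold: the number of more-similar alternative
#'   clusters a merge tolerates; default `log(n)`. Raising it makes merging
#'   more permissive (never more clusters).
#' @param z_merge homogeneity gate in standard errors.
#' @param size_gate cluster size from which the homogeneity gate is active;
#'   strata smaller than this are below the method's resolution.
#' @param absorb_frac relative-margin threshold of the splinter rescue.
#' @param splinter_ratio maximal size ratio (small/large) for an edge to be
#'   treated as a splinter reunion.
#' @return object of class `cluster_assignment`: list with `labels`
#'   (per-individual cluster id `1..n_clusters`) and `n_clusters`.
#' @export
hungarian_cluster <- function(sim, t_all = NULL, z_merge = 4, size_gate = 8,
                              absorb_frac = 0.5, splinter_ratio = 1 / 3) {
  sc <- .sim_scores(sim)
  n <- nrow(sc)
  if (n < 2) {
    warning("fewer than 2 individuals: returning a single cluster")
    return(structure(list(labels = rep(1L, n), n_clusters = min(n, 1L)),
                     class = "cluster_assignment"))
  }
  if (is.null(t_all)) t_all <- log(n)

  members <- as.list(seq_len(n))
  repeat {
    st <- .hc_level_stats(sc, members)
    m <- st$m
    if (m < 2) break
    A <- st$cross
    diag(A) <- -Inf
    B <- A - min(A[is.finite(A)])
    B[!is.finite(B)] <- -1e9
    sol <- solve_max_assignment(B)
    partner <- sol$pairs[order(sol$pairs[, "row"]), "col"]
    nn <- apply(A, 1, which.max)
    mnn <- cbind(seq_len(m), nn)[nn[nn] == seq_len(m), , drop = FALSE]
    edges <- unique(rbind(t(apply(cbind(seq_len(m), partner), 1, sort)),
                          t(apply(mnn, 1, sort))))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    accept <- logical(nrow(edges))
    for (e in seq_len(nrow(edges))) {
      c1 <- edges[e, 1]; c2 <- edges[e, 2]
      s_cd <- st$cross[c1, c2]
      t1 <- sum(st$cross[c1, -c(c1, c2)] > s_cd)
      t2 <- sum(st$cross[c2, -c(c1, c2)] > s_cd)
      if (t1 >= t_all || t2 >= t_all) next
      if (!.hc_edge_ok(st, c1, c2, z_merge, size_gate, absorb_frac, splinter_ratio)) next
      accept[e] <- TRUE
    }
    if (!any(accept)) break
    comp <- seq_len(m)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (e in which(accept)) {
      r1 <- find(edges[e, 1]); r2 <- find(edges[e, 2])
      if (r1 != r2) comp[r2] <- r1
    }
    roots <- vapply(seq_len(m), find, integer(1))
    members <- lapply(split(seq_len(m), roots),
                      function(ks) unlist(members[ks], use.names = FALSE))
    names(members) <- NULL
  }

  # absorb leftover sub-gate clusters into compatible dominant clusters
  repeat {
    st <- .hc_level_stats(sc, members)
    small <- which(st$sizes < size_gate)
    big <- which(st$sizes >= size_gate)
    if (length(small) == 0 || length(big) == 0) break
    moved <- FALSE
    for (cs in small) {
      ord <- big[order(st$cross[cs, big], decreasing = TRUE)]
      d <- ord[1]
      w_d <- st$within[d]
      if (!is.finite(w_d)) next
      b <- if (length(ord) > 1) st$cross[cs, ord[2]] else -Inf
      ok <- if (is.finite(b) && w_d - b > 0) {
        (st$cross[cs, d] - b) / (w_d - b) > absorb_frac
      } else TRUE
      if (ok) {
        members[[d]] <- c(members[[d]], members[[cs]])
        members[[cs]] <- NULL
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }

  labels <- integer(n)
  ord <- order(vapply(members, min, integer(1)))
  for (k in seq_along(ord)) labels[members[[ord[k]]]] <- k
  structure(list(labels = labels, n_clusters = length(members)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cluster(s) over %d individuals (sizes: %s)\n",
              x$n_clusters, length(x$labels),
              paste(sort(table(x$labels), decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Per-cluster case/control counts
#'
#' @param clusters a `cluster_assignment` (or label vector).
#' @param phen a [phenotype()] object.
#' @return data frame with columns `cluster`, `n_controls`, `n_cases`, `n`.
#' @export
cluster_summary <- function(clusters, phen) {
  labels <- .cluster_labels(clusters)
  stopifnot(length(labels) == length(phen$status))
  cl <- sort(unique(labels))
  out <- data.frame(
    cluster = cl,
    n_controls = vapply(cl, function(k) length(intersect(which(labels == k), controls(phen))), integer(1)),
    n_cases = vapply(cl, function(k) length(intersect(which(labels == k), cases(phen))), integer(1))
  )
  out$n <- out$n_controls + out$n_cases
  out
}

#' Cluster units for matched testing
#'
#' Turns a cluster assignment into a `unit_structure` of kind `"cluster"`:
#' one unit per cluster holding its cases and controls. Clusters lacking
#' either role are dropped (members removed).
#'
#' @inheritParams cluster_summary
#' @return a `unit_structure`.
#' @export
cluster_units <- function(clusters, phen) {
  labels <- .cluster_labels(clusters)
  units <- list()
  removed <- integer(0)
  for (k in sort(unique(labels))) {
    A <- intersect(which(labels == k), cases(phen))
    O <- intersect(which(labels == k), controls(phen))
    if (length(A) && length(O)) units[[length(units) + 1L]] <- list(cases = A, controls = O)
    else removed <- c(removed, A, O)
  }
  unit_structure(units, kind = "cluster", removed = removed,
                 n_ind = length(phen$status), ids = phen$ids)
}

#' Write / read a cluster assignment as TSV
#'
#' Columns `individual_id`, `cluster_id`.
#'
#' @param clusters a `cluster_assignment` (or label vector).
#' @param ids individual identifiers (writing: paired with labels; reading:
#'   defines the order of the returned labels).
#' @param path file path.
#' @return `read_clusters_tsv()` returns a `cluster_assignment`.
#' @export
write_clusters_tsv <- function(clusters, ids, path) {
  labels <- .cluster_labels(clusters)
  stopifnot(length(ids) == length(labels))
  write.table(data.frame(individual_id = ids, cluster_id = labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters_tsv
#' @export
read_clusters_tsv <- function(path, ids) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  idx <- match(ids, df$individual_id)
  if (anyNA(idx)) stop("cluster file does not cover all individuals")
  labels <- as.integer(df$cluster_id[idx])
  structure(list(labels = labels, n_clusters = length(unique(labels))),
            class = "cluster_assignment")
}
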