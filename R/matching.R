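# Case-control structuring: optimal pairs, iterative groups, and the
# vicinity / intra-cluster stratum validation strategies.

#' Matched unit structure
#'
#' A partition of (a subset of) the sample into units -- pairs, groups or
#' clusters -- each containing at least one case and one control. Individuals
#' outside every unit are listed in `removed` and are excluded from testing.
#'
#' @param units list of units; each unit is a list with integer index vectors
#'   `cases` and `controls`.
#' @param kind `"pair"`, `"group"` or `"cluster"`.
#' @param removed integer indices of unmatched individuals.
#' @param n_ind sample size the indices refer to.
#' @param ids optional individual identifiers.
#' @return object of class `unit_structure`.
#' @export
unit_structure <- function(units, kind = c("pair", "group", "cluster"),
                           removed = integer(0), n_ind, ids = NULL) {
  kind <- match.arg(kind)
  all_members <- integer(0)
  for (u in units) {
    if (length(u$cases) < 1 || length(u$controls) < 1) {
      stop("every unit must contain at least one case and one control")
    }
    if (kind == "pair" && (length(u$cases) != 1 || length(u$controls) != 1)) {
      stop("pair units must contain exactly one case and one control")
    }
    all_members <- c(all_members, u$cases, u$controls)
  }
  if (anyDuplicated(all_members)) stop("units must be pairwise disjoint")
  if (length(all_members) && max(all_members) > n_ind) stop("unit index out of range")
  structure(list(units = units, kind = kind,
                 removed = sort(unique(as.integer(removed))),
                 n_ind = as.integer(n_ind), ids = ids),
            class = "unit_structure")
}

#' @export
print.unit_structure <- function(x, ...) {
  sizes <- vapply(x$units, function(u) length(u$cases) + length(u$controls), integer(1))
  cat(sprintf("unit_structure: %d %s unit(s), %d matched individuals, %d removed\n",
              length(x$units), x$kind, sum(sizes), length(x$removed)))
  invisible(x)
}

#' @rdname unit_structure
#' @param structure a `unit_structure`.
#' @return `unit_index()`: integer vector mapping each individual to its unit
#'   (1-based; `NA` outside every unit).
#' @export
unit_index <- function(structure) {
  idx <- rep(NA_integer_, structure$n_ind)
  for (k in seq_along(structure$units)) {
    u <- structure$units[[k]]
    idx[c(u$cases, u$controls)] <- k
  }
  idx
}

.matched_members <- function(structure) which(!is.na(unit_index(structure)))

#' Optimal case-control pairwise matching
#'
#' Matches cases to controls by maximum total IBS using the assignment
#' solver. Unequal sides are balanced with zero-weight sinks; sink-matched
#' individuals end up in `removed`, leaving `min(|O|, |A|)` one-to-one pairs.
#' Run [validate_units()] afterwards for stratum validation.
#'
#' @param sim a `similarity_matrix` (or plain score matrix).
#' @param phen a [phenotype()] object.
#' @return a `unit_structure` of kind `"pair"`.
#' @export
match_pairs <- function(sim, phen) {
  sc <- .sim_scores(sim)
  A <- cases(phen); O <- controls(phen)
  if (length(A) == 0 || length(O) == 0) stop("need at least one case and one control")
  padded <- pad_with_sinks(sc[A, O, drop = FALSE])
  sol <- solve_max_assignment(padded$weights)
  keep <- !(sol$pairs[, "row"] %in% padded$sink_rows) &
          !(sol$pairs[, "col"] %in% padded$sink_cols)
  real <- sol$pairs[keep, , drop = FALSE]
  units <- lapply(seq_len(nrow(real)), function(k) {
    list(cases = A[real[k, "row"]], controls = O[real[k, "col"]])
  })
  matched <- unlist(lapply(units, function(u) c(u$cases, u$controls)))
  removed <- setdiff(c(A, O), matched)
  unit_structure(units, kind = "pair", removed = removed,
                 n_ind = length(phen$status), ids = phen$ids)
}

#' Vicinity threshold
#'
#' `T_cc = ln(|O| |A|)`, the abundance threshold of better-scoring mates a
#' valid pair may tolerate.
#'
#' @param n_controls,n_cases sizes of the control and case sets (>= 1).
#' @return the threshold value.
#' @examples
#' vicinity_threshold(10, 10)  # log(100)
#' @export
vicinity_threshold <- function(n_controls, n_cases) {
  if (n_controls < 1 || n_cases < 1) stop("both sets must be non-empty")
  log(as.numeric(n_controls) * as.numeric(n_cases))
}

#' Vicinity check for one case-control pair
#'
#' Counts, over the full sets, the controls with a strictly higher score to
#' the case than its matched control (`t_x`), and the cases with a strictly
#' higher score to the control than its matched case (`t_y`). The pair is
#' valid when `(t_x < T_cc & t_y < T_cc) | t_x == 0 | t_y == 0`.
#'
#' @param case,control individual indices (phenotype-discordant).
#' @param sim similarity matrix.
#' @param phen phenotype.
#' @param t_cc threshold; default [vicinity_threshold()] on the full sets.
#' @return logical validity flag, with attributes `t_x`, `t_y`.
#' @export
vicinity_check <- function(case, control, sim, phen, t_cc = NULL) {
  sc <- .sim_scores(sim)
  A <- cases(phen); O <- controls(phen)
  if (is.null(t_cc)) t_cc <- vicinity_threshold(length(O), length(A))
  w <- sc[case, control]
  t_x <- sum(sc[case, O] > w)
  t_y <- sum(sc[A, control] > w)
  valid <- (t_x < t_cc && t_y < t_cc) || t_x == 0 || t_y == 0
  structure(valid, t_x = t_x, t_y = t_y)
}

#' Stratum validation of a unit structure
#'
#' `strategy = "cluster"` keeps only units whose members all share one
#' cluster; `strategy = "vicinity"` applies [vicinity_check()] to every
#' case-control pair inside each unit and keeps units whose pairs all pass.
#' Members of rejected units are reported in `rejected` and added to the
#' structure's `removed` set.
#'
#' @param structure a `unit_structure`.
#' @param sim similarity matrix (used by the vicinity strategy).
#' @param phen phenotype.
#' @param strategy `"cluster"` or `"vicinity"`.
#' @param clusters cluster labels (required for `strategy = "cluster"`).
#' @param t_cc vicinity threshold; defaults to the full-sample
#'   [vicinity_threshold()].
#' @return list with `structure` (validated) and `rejected` (indices).
#' @export
validate_units <- function(structure, sim, phen,
                           strategy = c("cluster", "vicinity"),
                           clusters = NULL, t_cc = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "cluster" && is.null(clusters)) {
    stop("cluster validation requires a cluster assignment")
  }
  if (strategy == "vicinity" && is.null(t_cc)) {
    t_cc <- vicinity_threshold(length(controls(phen)), length(cases(phen)))
  }
  labels <- if (!is.null(clusters)) .cluster_labels(clusters) else NULL
  ok <- vapply(structure$units, function(u) {
    if (strategy == "cluster") {
      length(unique(labels[c(u$cases, u$controls)])) == 1L
    } else {
      all(vapply(u$cases, function(x) {
        all(vapply(u$controls, function(y) {
          isTRUE(as.logical(vicinity_check(x, y, sim, phen, t_cc)))
        }, logical(1)))
      }, logical(1)))
    }
  }, logical(1))
  rejected <- unlist(lapply(structure$units[!ok],
                            function(u) c(u$cases, u$controls)))
  if (is.null(rejected)) rejected <- integer(0)
  out <- unit_structure(structure$units[ok], kind = structure$kind,
                        removed = c(structure$removed, rejected),
                        n_ind = structure$n_ind, ids = structure$ids)
  list(structure = out, rejected = sort(rejected))
}

#' Intra-cluster pairwise matching
#'
#' Runs [match_pairs()] separately inside each cluster, which enforces that
#' every pair originates from one stratum. Clusters lacking cases or controls
#' contribute nothing; their members are removed.
#'
#' @inheritParams validate_units
#' @return a `unit_structure` of kind `"pair"`.
#' @export
match_within_clusters <- function(sim, phen, clusters) {
  labels <- .cluster_labels(clusters)
  sc <- .sim_scores(sim)
  n <- length(phen$status)
  stopifnot(length(labels) == n)
  units <- list()
  removed <- integer(0)
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    A <- intersect(members, cases(phen))
    O <- intersect(members, controls(phen))
    if (length(A) == 0 || length(O) == 0) {
      removed <- c(removed, intersect(members, c(cases(phen), controls(phen))))
      next
    }
    sub <- phenotype(ifelse(seq_len(n) %in% A, 1L,
                            ifelse(seq_len(n) %in% O, 0L, NA)), ids = phen$ids)
    ms <- match_pairs(sim, sub)
    units <- c(units, ms$units)
    removed <- c(removed, ms$removed)
  }
  unit_structure(units, kind = "pair", removed = removed,
                 n_ind = n, ids = phen$ids)
}

# propose an assignment between anchors (in units) and pool (unmatched),
# returning valid (anchor, candidate) edges under the chosen validation
.rematch_round <- function(sc, phen, anchors, pool, anchor_is_case,
                           validation, labels, t_cc, sim) {
  if (length(anchors) == 0 || length(pool) == 0) return(NULL)
  w <- sc[anchors, pool, drop = FALSE]
  padded <- pad_with_sinks(w)
  sol <- solve_max_assignment(padded$weights)
  keep <- !(sol$pairs[, "row"] %in% padded$sink_rows) &
          !(sol$pairs[, "col"] %in% padded$sink_cols)
  real <- sol$pairs[keep, , drop = FALSE]
  if (nrow(real) == 0) return(NULL)
  edges <- cbind(anchor = anchors[real[, "row"]], cand = pool[real[, "col"]])
  ok <- vapply(seq_len(nrow(edges)), function(k) {
    x <- edges[k, "anchor"]; y <- edges[k, "cand"]
    if (validation == "cluster") {
      labels[x] == labels[y]
    } else {
      cs <- if (anchor_is_case) x else y
      co <- if (anchor_is_case) y else x
      isTRUE(as.logical(vicinity_check(cs, co, sim, phen, t_cc)))
    }
  }, logical(1))
  edges[ok, , drop = FALSE]
}

#' Iterative case-control groupwise matching
#'
#' Starts from a validated pairwise matching, then repeatedly re-matches
#' unmatched controls to already-matched cases and unmatched cases to
#' already-matched controls. Each new edge is validated (same cluster, or
#' vicinity check on the new case-control pair with the original full-sample
#' threshold); a valid candidate joins the existing unit of its matched
#' partner. Iteration stops when everyone is matched or a full round adds no
#' one. Units may therefore hold more than one case and one control.
#'
#' @inheritParams validate_units
#' @param validation `"cluster"` (requires `clusters`; all matching is then
#'   confined within clusters) or `"vicinity"`.
#' @return a `unit_structure` of kind `"group"`.
#' @export
match_groups <- function(sim, phen, validation = c("cluster", "vicinity"),
                         clusters = NULL, t_cc = NULL) {
  validation <- match.arg(validation)
  sc <- .sim_scores(sim)
  A <- cases(phen); O <- controls(phen)
  if (length(A) == 0 || length(O) == 0) stop("need at least one case and one control")
  if (validation == "cluster") {
    if (is.null(clusters)) stop("cluster validation requires a cluster assignment")
    labels <- .cluster_labels(clusters)
    init <- match_within_clusters(sim, phen, clusters)
  } else {
    labels <- NULL
    if (is.null(t_cc)) t_cc <- vicinity_threshold(length(O), length(A))
    init <- validate_units(match_pairs(sim, phen), sim, phen,
                           strategy = "vicinity", t_cc = t_cc)$structure
  }
  units <- init$units
  max_rounds <- length(A) + length(O)
  for (round in seq_len(max_rounds)) {
    if (length(units) == 0) break
    uidx <- rep(NA_integer_, length(phen$status))
    for (k in seq_along(units)) uidx[c(units[[k]]$cases, units[[k]]$controls)] <- k
    matched_cases <- intersect(which(!is.na(uidx)), A)
    matched_controls <- intersect(which(!is.na(uidx)), O)
    pool_cases <- setdiff(A, matched_cases)
    pool_controls <- setdiff(O, matched_controls)
    added <- 0L
    # one direction of a round: cluster validation confines the assignment to
    # each cluster; vicinity proposes globally and validates each new edge
    propose <- function(anchors, pool, anchor_is_case) {
      if (validation == "cluster") {
        out <- NULL
        for (cl in unique(labels[anchors])) {
          e <- .rematch_round(sc, phen,
                              anchors[labels[anchors] == cl],
                              pool[labels[pool] == cl],
                              anchor_is_case, validation, labels, t_cc, sim)
          if (!is.null(e)) out <- rbind(out, e)
        }
        out
      } else {
        .rematch_round(sc, phen, anchors, pool, anchor_is_case,
                       validation, labels, t_cc, sim)
      }
    }
    e1 <- propose(matched_cases, pool_controls, TRUE)
    if (!is.null(e1) && nrow(e1) > 0) {
      for (k in seq_len(nrow(e1))) {
        u <- uidx[e1[k, "anchor"]]
        units[[u]]$controls <- c(units[[u]]$controls, e1[k, "cand"])
      }
      added <- added + nrow(e1)
      for (k in seq_along(units)) uidx[c(units[[k]]$cases, units[[k]]$controls)] <- k
    }
    e2 <- propose(matched_controls, setdiff(A, which(!is.na(uidx))), FALSE)
    if (!is.null(e2) && nrow(e2) > 0) {
      for (k in seq_len(nrow(e2))) {
        u <- uidx[e2[k, "anchor"]]
        units[[u]]$cases <- c(units[[u]]$cases, e2[k, "cand"])
      }
      added <- added + nrow(e2)
    }
    if (added == 0L) break
  }
  matched <- unlist(lapply(units, function(u) c(u$cases, u$controls)))
  removed <- setdiff(c(A, O), matched)
  unit_structure(units, kind = "group", removed = removed,
                 n_ind = length(phen$status), ids = phen$ids)
}

#' Write / read a unit structure as TSV
#'
#' Exchange format between the matching and testing stages: one row per
#' matched individual with columns `individual_id`, `unit_id`, `role`.
#'
#' @param structure a `unit_structure` (with `ids` set).
#' @param path file path.
#' @param ids full individual id vector, defining the index space on read.
#' @param kind unit kind to stamp on the structure read back.
#' @return `read_units_tsv()` returns a `unit_structure`.
#' @export
write_units_tsv <- function(structure, path) {
  ids <- structure$ids
  if (is.null(ids)) ids <- as.character(seq_len(structure$n_ind))
  rows <- do.call(rbind, lapply(seq_along(structure$units), function(k) {
    u <- structure$units[[k]]
    data.frame(individual_id = ids[c(u$cases, u$controls)],
               unit_id = k,
               role = rep(c("case", "control"), c(length(u$cases), length(u$controls))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(individual_id = character(0),
                                        unit_id = integer(0), role = character(0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_units_tsv
#' @export
read_units_tsv <- function(path, ids, kind = "group") {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  idx <- match(df$individual_id, ids)
  if (anyNA(idx)) stop("unit file refers to unknown individual id(s)")
  units <- lapply(split(seq_len(nrow(df)), df$unit_id), function(r) {
    list(cases = idx[r][df$role[r] == "case"],
         controls = idx[r][df$role[r] == "control"])
  })
  names(units) <- NULL
  matched <- unlist(lapply(units, function(u) c(u$cases, u$controls)))
  unit_structure(units, kind = kind,
                 removed = setdiff(seq_along(ids), matched),
                 n_ind = length(ids), ids = ids)
}
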