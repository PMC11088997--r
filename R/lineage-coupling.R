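#' Observed shared-barcode matrix
#'
#' \code{O[i, j]} counts clones (barcodes) with at least one cell in state
#' \code{i} and at least one cell in state \code{j}; a barcode is shared
#' when it appears in at least one cell from both states. The diagonal
#' \code{O[i, i]} counts clones present in state \code{i}, so the marginals
#' reflect clone-state incidence.
#'
#' @param clone_table data.frame with clone_id and a state column.
#' @param states ordered state labels; defaults to the sorted states present.
#'   Required when the clone table is empty.
#' @param state_col column holding the state label (default \code{"class"}).
#' @return symmetric integer matrix with \code{states} dimnames.
#' @export
observed_shared_matrix <- function(clone_table, states = NULL,
                                   state_col = "class") {
  if (is.null(states)) {
    if (nrow(clone_table) == 0L)
      stop("states must be given for an empty clone table")
    states <- sort(unique(clone_table[[state_col]]))
  }
  if (!length(states)) stop("states must be nonempty")
  if (nrow(clone_table) == 0L) {
    O <- matrix(0L, length(states), length(states),
                dimnames = list(states, states))
    return(O)
  }
  bad <- setdiff(unique(clone_table[[state_col]]), states)
  if (length(bad))
    stop("cell states not in `states`: ", paste(bad, collapse = ", "))
  B <- clone_state_incidence(clone_table, states, state_col)
  O <- crossprod(B)
  storage.mode(O) <- "integer"
  dimnames(O) <- list(states, states)
  O
}

# clones x states 0/1 incidence matrix
clone_state_incidence <- function(clone_table, states, state_col = "class") {
  clones <- sort(unique(clone_table$clone_id))
  B <- matrix(0L, length(clones), length(states),
              dimnames = list(clones, states))
  B[cbind(match(clone_table$clone_id, clones),
          match(clone_table[[state_col]], states))] <- 1L
  B
}

#' Expected shared-barcode matrix under no lineage coupling
#'
#' Independence expectation from the observed matrix's own marginals:
#' \code{E[i, j] = rowsum_i * colsum_j / grandtotal}. Under this null the
#' observed/expected ratio is 1, a ratio above 1 indicates positive lineage
#' coupling between the two states and below 1 negative coupling. The
#' grand-total denominator makes \code{sum(E) == sum(O)} exactly.
#'
#' @param O symmetric nonnegative matrix from
#'   \code{\link{observed_shared_matrix}}.
#' @return numeric matrix \code{E}; when \code{sum(O) == 0} every entry is
#'   \code{NA} and the attribute \code{undefined} is set (no division
#'   error).
#' @export
expected_matrix <- function(O) {
  if (!is.matrix(O) || nrow(O) != ncol(O))
    stop("O must be a square matrix")
  if (max(abs(O - t(O))) > 0) stop("O must be symmetric")
  if (any(O < 0)) stop("O must be nonnegative")
  total <- sum(O)
  if (total == 0) {
    E <- matrix(NA_real_, nrow(O), ncol(O), dimnames = dimnames(O))
    attr(E, "undefined") <- TRUE
    return(E)
  }
  E <- outer(rowSums(O), colSums(O)) / total
  dimnames(E) <- dimnames(O)
  E
}

#' Lineage-coupling analysis with a subsampled resampling null
#'
#' Recomputes the observed and expected shared-barcode matrices over
#' \code{n_trials} random subsamples of the clones (default 1,000 trials of
#' a 25\% sample, drawn without replacement) and summarises each state pair
#' by the median observed/expected ratio across trials. Empirical p-values
#' count the trials on the opposite side of 1 from the pair's coupling
#' direction — ratios above 1 for negatively coupled pairs, below 1 for
#' positively coupled pairs — with a pseudo-count:
#' \code{p = (k + 1) / (n_valid + 1)}. Off-diagonal p-values are
#' Benjamini-Hochberg adjusted.
#'
#' @inheritParams observed_shared_matrix
#' @param n_trials number of subsampling trials (default 1000).
#' @param frac clone fraction per trial (default 0.25).
#' @param seed integer seed; fully determines the result.
#' @param diag_mode \code{"incidence"} keeps the clone-presence diagonal in
#'   the marginals; \code{"strict"} zeroes the diagonal before computing
#'   marginals.
#' @return object of class \code{coupling_result}: state list, full-data
#'   \code{O} and \code{E}, symmetric \code{score}, \code{p} and \code{q}
#'   matrices (diagonal \code{NA}), per-pair valid-trial counts, and the
#'   trial settings. Pairs with zero valid trials have \code{NA} score and
#'   p.
#' @export
coupling_analysis <- function(clone_table, states = NULL, n_trials = 1000,
                              frac = 0.25, seed = 1, state_col = "class",
                              diag_mode = c("incidence", "strict")) {
  diag_mode <- match.arg(diag_mode)
  stopifnot(n_trials >= 1, frac > 0, frac <= 1)
  if (is.null(states)) states <- sort(unique(clone_table[[state_col]]))
  ns <- length(states)
  B <- clone_state_incidence(clone_table, states, state_col)
  n_clones <- nrow(B)
  if (n_clones == 0L) stop("no clones in the clone table")
  m <- ceiling(frac * n_clones)
  pair_idx <- which(upper.tri(matrix(0, ns, ns)))
  ratios <- matrix(NA_real_, n_trials, length(pair_idx))
  set.seed(derive_seed(seed, 4L))
  for (t in seq_len(n_trials)) {
    idx <- sample.int(n_clones, m)
    Ot <- crossprod(B[idx, , drop = FALSE])
    Et <- trial_expected(Ot, diag_mode)
    r <- (Ot / Et)[pair_idx]
    r[!is.finite(r)] <- NA_real_   # E == 0 (or 0/0): trial invalid for pair
    ratios[t, ] <- r
  }
  n_valid <- colSums(!is.na(ratios))
  score_v <- apply(ratios, 2L, median, na.rm = TRUE)
  score_v[n_valid == 0L] <- NA_real_
  p_v <- rep(NA_real_, length(pair_idx))
  for (j in seq_along(pair_idx)) {
    if (n_valid[j] == 0L) next
    r <- ratios[!is.na(ratios[, j]), j]
    # trials on the opposite side of 1; ties (ratio exactly 1) carry no
    # evidence of coupling and count toward the null side
    k <- if (score_v[j] >= 1) sum(r <= 1) else sum(r >= 1)
    p_v[j] <- (k + 1) / (n_valid[j] + 1)
  }
  q_v <- rep(NA_real_, length(p_v))
  ok <- !is.na(p_v)
  q_v[ok] <- p.adjust(p_v[ok], method = "BH")

  to_sym <- function(v, diag = NA_real_) {
    M <- matrix(diag, ns, ns, dimnames = list(states, states))
    M[pair_idx] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  O <- crossprod(B)
  dimnames(O) <- list(states, states)
  structure(list(states = states, O = O,
                 E = trial_expected(O, diag_mode),
                 score = to_sym(score_v), p = to_sym(p_v), q = to_sym(q_v),
                 n_valid_trials = to_sym(n_valid), n_trials = n_trials,
                 frac = frac, seed = seed, diag_mode = diag_mode),
            class = "coupling_result")
}

trial_expected <- function(O, diag_mode) {
  Om <- O
  if (diag_mode == "strict") diag(Om) <- 0
  total <- sum(Om)
  if (total == 0) return(matrix(NA_real_, nrow(O), ncol(O)))
  outer(rowSums(Om), colSums(Om)) / total
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("Lineage-coupling analysis\n")
  cat(sprintf("  states: %s\n", paste(x$states, collapse = ", ")))
  cat(sprintf("  %d trials x %.0f%% clone subsample (seed %d, %s diagonal)\n",
              x$n_trials, 100 * x$frac, x$seed, x$diag_mode))
  cat("  median O/E scores:\n")
  print(round(x$score, 3))
  cat("  BH-adjusted empirical p (off-diagonal):\n")
  print(signif(x$q, 3))
  invisible(x)
}

#' @export
summary.coupling_result <- function(object, ...) {
  ns <- length(object$states)
  ut <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  data.frame(state_i = object$states[ut[, 1]],
             state_j = object$states[ut[, 2]],
             observed = object$O[ut],
             expected = object$E[ut],
             score = object$score[ut],
             p = object$p[ut], q = object$q[ut],
             n_valid_trials = object$n_valid_trials[ut],
             stringsAsFactors = FALSE)
}
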