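#' Generate a lineage-barcode library
#'
#' Draws \code{n} distinct barcodes matching the bridge layout at its fixed
#' positions, rejection-sampling the random positions so that every pair of
#' library barcodes differs at no fewer than \code{min_pairwise_hamming}
#' positions. The default separation of 7 (= 2 * 3 + 1) guarantees that
#' single-linkage clusters at Hamming distance 3 cannot merge two library
#' barcodes even when every read carries up to 3 errors.
#'
#' @param n number of barcodes.
#' @param layout a \code{\link{bridge_layout}}.
#' @param min_pairwise_hamming minimum pairwise Hamming distance.
#' @param seed integer seed.
#' @param max_rejections bound on consecutive rejected candidates before the
#'   combination is declared unsatisfiable.
#' @return character vector of \code{n} distinct barcode sequences.
#' @export
generate_barcode_library <- function(n, layout = default_bridge_layout(),
                                     min_pairwise_hamming = 7, seed = 1,
                                     max_rejections = 10000) {
  stopifnot(n >= 0, min_pairwise_hamming >= 0)
  n <- as.integer(n)
  if (n == 0L) return(character(0))
  mask <- layout_random_mask(layout)
  n_random <- sum(mask)
  if (min_pairwise_hamming > n_random && n > 1L)
    stop("min_pairwise_hamming exceeds the number of random positions")
  template <- layout_template(layout)
  set.seed(derive_seed(seed, 0L))
  lib <- character(0)
  lib_mat <- NULL   # random positions of accepted barcodes, rows = barcodes
  rejections <- 0L
  bases <- c("A", "C", "G", "T")
  while (length(lib) < n) {
    cand <- sample(bases, n_random, replace = TRUE)
    ok <- TRUE
    if (!is.null(lib_mat)) {
      d <- rowSums(sweep(lib_mat, 2L, cand, `!=`))
      ok <- all(d >= min_pairwise_hamming)
    }
    if (ok) {
      seqv <- template
      seqv[mask] <- cand
      lib <- c(lib, paste(seqv, collapse = ""))
      lib_mat <- rbind(lib_mat, cand)
      rejections <- 0L
    } else {
      rejections <- rejections + 1L
      if (rejections > max_rejections)
        stop(sprintf(
          "could not place barcode %d of %d at min_pairwise_hamming = %d; ",
          length(lib) + 1L, n, min_pairwise_hamming),
          "the (n, min_pairwise_hamming) combination looks unsatisfiable")
    }
  }
  lib
}

#' Simulate clone structure with known ground truth
#'
#' Draws \code{n_progenitors} clones per batch and arm, clone sizes from the
#' configured size law, and each cell's class from the arm's class
#' probabilities (the perturbed arm uses the control probabilities with
#' \code{fate_shift_delta} moved from PN to the IN classes). The shift acts
#' on whole clones as they are generated: every cell of a perturbed-arm
#' clone is drawn from the shifted probabilities, matching a clone-level
#' reading of fate switching.
#'
#' Optional \code{coupling} entries bias clones of size >= 2 so that a state
#' pair co-occurs within clones at \code{factor} times its independence
#' rate: after the iid class draw, a clone lacking the pair is upgraded to
#' contain both states with the probability that brings the co-occurrence
#' rate to the target (capped at 1).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{clone_table} (data.frame: cell_id, clone_id,
#'   class, arm, batch) and \code{truth} (delta, per-arm class
#'   probabilities, coupling settings).
#' @export
simulate_clones <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  size_vals <- as.integer(names(config$clone_size_law))
  arm_probs <- list(config$class_probs_control, perturbed_class_probs(config))
  names(arm_probs) <- config$arm_labels
  blocks <- vector("list", 0L)
  clone_counter <- 0L
  for (b in seq_len(config$n_batches)) {
    batch <- sprintf("batch%02d", b)
    for (arm in config$arm_labels) {
      p <- arm_probs[[arm]]
      classes <- names(p)
      np <- config$n_progenitors
      sizes <- size_vals[sample.int(length(size_vals), np, replace = TRUE,
                                    prob = config$clone_size_law)]
      cls <- if (is.null(config$coupling)) {
        sample(classes, sum(sizes), replace = TRUE, prob = p)
      } else {
        unlist(lapply(sizes, function(s)
          apply_coupling(s, p, config$coupling)))
      }
      clone_idx <- clone_counter + rep.int(seq_len(np), sizes)
      blocks[[length(blocks) + 1L]] <- data.frame(
        cell_id = sprintf("cell_%06d_%02d", clone_idx,
                          sequence(sizes)),
        clone_id = sprintf("%s:true%05d", batch, clone_idx),
        class = cls, arm = arm, batch = batch,
        stringsAsFactors = FALSE)
      clone_counter <- clone_counter + np
    }
  }
  clone_table <- do.call(rbind, blocks)
  rownames(clone_table) <- NULL
  truth <- list(fate_shift_delta = config$fate_shift_delta,
                class_probs = arm_probs,
                coupling = config$coupling)
  list(clone_table = clone_table, truth = truth)
}

# Couple configured state pairs at the clone-incidence level. For a pair
# (a, b) with iid clone-membership probabilities qa(s) = 1 - (1-pa)^s and
# qb(s), membership is drawn from the dependent Bernoulli pair with
# P(a and b) = factor * qa * qb (capped at the Frechet bounds) and the
# marginals held exactly at qa, qb — so the pair co-occurs at `factor`
# times its independence rate without inflating either state's prevalence.
# Cells are then drawn to realise the membership: one cell per required
# state, the rest iid over the non-banned states.
apply_coupling <- function(s, p, coupling) {
  forced <- character(0)
  banned <- character(0)
  for (cp in coupling) {
    a <- cp$states[1]; b <- cp$states[2]
    qa <- 1 - (1 - p[[a]])^s
    qb <- 1 - (1 - p[[b]])^s
    p11 <- if (s < 2L) qa * qb else min(cp$factor * qa * qb, qa, qb)
    p11 <- max(p11, qa + qb - 1)   # Frechet lower bound
    has_a <- runif(1) < qa
    has_b <- if (has_a) runif(1) < p11 / qa else
      runif(1) < (qb - p11) / (1 - qa)
    if (s < 2L && has_a && has_b) has_b <- FALSE  # one cell, one state
    forced <- c(forced, if (has_a) a, if (has_b) b)
    banned <- c(banned, if (!has_a) a, if (!has_b) b)
  }
  n_forced <- length(forced)
  if (n_forced > s) forced <- forced[seq_len(s)]
  allowed <- setdiff(names(p), banned)
  pa <- p[allowed] / sum(p[allowed])
  rest <- if (s > length(forced))
    sample(allowed, s - length(forced), replace = TRUE, prob = pa) else
    character(0)
  sample(c(forced, rest))
}

#' Synthesize barcode reads for a clone table
#'
#' Each clone is tied to one library barcode; each cell emits
#' \code{reads_per_cell} reads of the form 5' anchor + barcode + 3' anchor,
#' with iid per-base substitution errors at \code{per_base_error} applied to
#' the barcode portion. Each cell owns a pool of \code{umis_per_barcode}
#' distinct UMIs from which reads sample with replacement (PCR jackpotting).
#' Phred scores are drawn per base from the configured quality model.
#'
#' @param clone_table data.frame as from \code{\link{simulate_clones}}.
#' @param barcodes library barcodes, at least one per distinct clone.
#' @param config a \code{\link{sim_config}}.
#' @param anchor5,anchor3 fixed anchor sequences flanking the barcode.
#' @return list with \code{reads} (data.frame: read_id, sequence, quality,
#'   cell_id, umi) and \code{truth} (data.frame: read_id, cell_id, clone_id,
#'   true_barcode).
#' @export
synthesize_fastq <- function(clone_table, barcodes, config,
                             anchor5 = "TCGATCCGGA", anchor3 = "AGCTTGGCGT") {
  stopifnot(inherits(config, "sim_config"))
  clones <- sort(unique(clone_table$clone_id))
  if (length(barcodes) < length(clones))
    stop("need at least one library barcode per clone")
  set.seed(derive_seed(config$seed, 2L))
  clone_bc <- setNames(barcodes[seq_along(clones)], clones)
  n_cells <- nrow(clone_table)
  rpc <- config$reads_per_cell
  n_reads <- n_cells * rpc
  bl <- config$barcode_length
  cell_of_read <- rep(clone_table$cell_id, each = rpc)
  clone_of_read <- rep(clone_table$clone_id, each = rpc)
  true_bc <- unname(clone_bc[clone_of_read])

  # UMI pool per cell, sampled per read
  umi_pool <- matrix(
    replicate(n_cells * config$umis_per_barcode, random_umi()),
    nrow = n_cells, byrow = TRUE)
  umi_idx <- sample.int(config$umis_per_barcode, n_reads, replace = TRUE)
  umi <- umi_pool[cbind(rep(seq_len(n_cells), each = rpc), umi_idx)]

  # substitution errors on the barcode portion
  bc_mat <- matrix(unlist(strsplit(true_bc, "")), nrow = n_reads, byrow = TRUE)
  err <- matrix(runif(n_reads * bl) < config$per_base_error, n_reads, bl)
  if (any(err)) {
    k <- sum(err)
    # substitute with one of the three other bases, uniformly
    shift <- sample.int(3L, k, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    old <- match(bc_mat[err], bases)
    bc_mat[err] <- bases[((old - 1L + shift) %% 4L) + 1L]
  }
  bc_read <- apply(bc_mat, 1L, paste, collapse = "")
  sequence <- paste0(anchor5, bc_read, anchor3)

  read_len <- nchar(anchor5) + bl + nchar(anchor3)
  qm <- config$quality_model
  qint <- matrix(pmin(41L, pmax(2L, as.integer(round(
    rnorm(n_reads * read_len, qm[["mean"]], qm[["sd"]]))))),
    n_reads, read_len)
  quality <- apply(qint, 1L, int_to_phred)

  reads <- data.frame(read_id = sprintf("read_%07d", seq_len(n_reads)),
                      sequence = sequence, quality = quality,
                      cell_id = cell_of_read, umi = umi,
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = reads$read_id, cell_id = cell_of_read,
                      clone_id = clone_of_read, true_barcode = true_bc,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

random_umi <- function(len = 10L) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a cell-by-gene count matrix with known informative genes
#'
#' Non-informative genes share one negative-binomial mean across classes;
#' informative genes differ between PN and IN cells by
#' \code{informative_log2fc} (half up in PN, half up in IN), applied
#' symmetrically around the gene's base mean. Cells of other classes
#' (e.g. mitotic) sit at the base mean.
#'
#' @param clone_table data.frame with \code{cell_id} and \code{class}.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{counts} (sparse dgCMatrix, genes x cells) and
#'   \code{gene_truth} (data.frame: gene, informative, log2fc signed PN/IN).
#' @export
simulate_expression <- function(clone_table, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  ng <- config$n_genes
  ni <- config$n_informative_genes
  if (ni > ng) stop("n_informative_genes exceeds n_genes")
  genes <- sprintf("gene_%05d", seq_len(ng))
  cells <- clone_table$cell_id
  cls <- clone_table$class
  is_in <- grepl("^IN", cls)
  is_pn <- cls == "PN"

  informative <- sort(sample.int(ng, ni))
  # signed log2fc: positive = up in PN relative to IN
  lfc <- numeric(ng)
  signs <- rep(c(1, -1), length.out = ni)
  lfc[informative] <- signs * config$informative_log2fc

  base_mean <- exp(rnorm(ng, log(0.8), 0.6))
  # informative genes get a higher floor so the signal is recoverable
  base_mean[informative] <- pmax(base_mean[informative], 1)

  mu <- matrix(base_mean, ng, length(cells))
  fc_half <- 2^(lfc / 2)
  mu[, is_pn] <- base_mean * fc_half
  mu[, is_in] <- base_mean / fc_half

  counts <- matrix(rnbinom(length(mu), size = config$nb_size, mu = mu),
                   ng, length(cells), dimnames = list(genes, cells))
  gene_truth <- data.frame(gene = genes,
                           informative = seq_len(ng) %in% informative,
                           log2fc = lfc, stringsAsFactors = FALSE)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       gene_truth = gene_truth)
}
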