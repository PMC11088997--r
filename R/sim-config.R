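#' Lineage-barcode bridge layout
#'
#' A lineage barcode is a fixed-length synthetic oligo (37 bp by default) in
#' which short random stretches are bridged by fixed nucleotides. The exact
#' fixed/random arrangement is protocol-specific, so it is configured as an
#' ordered list of segments, each either \code{fixed} (a literal sequence)
#' or \code{random} (a length).
#'
#' @param ... segments in 5'-to-3' order, each created by
#'   \code{fixed_segment()} or \code{random_segment()}.
#' @return an object of class \code{bridge_layout}.
#' @examples
#' bridge_layout(random_segment(9), fixed_segment("GTAC"), random_segment(8),
#'               fixed_segment("CATG"), random_segment(8), fixed_segment("TGCA"))
#' @export
bridge_layout <- function(...) {
  segs <- list(...)
  if (!length(segs)) stop("bridge_layout needs at least one segment")
  ok <- vapply(segs, function(s) is.list(s) && s$kind %in% c("fixed", "random"),
               logical(1))
  if (!all(ok)) stop("segments must come from fixed_segment()/random_segment()")
  structure(list(segments = segs), class = "bridge_layout")
}

#' @rdname bridge_layout
#' @param seq literal A/C/G/T sequence of a fixed segment.
#' @export
fixed_segment <- function(seq) {
  if (!grepl("^[ACGT]+$", seq)) stop("fixed segment must be A/C/G/T")
  list(kind = "fixed", seq = seq, len = nchar(seq))
}

#' @rdname bridge_layout
#' @param len length of a random segment in bases.
#' @export
random_segment <- function(len) {
  len <- as.integer(len)
  if (len < 1L) stop("random segment length must be >= 1")
  list(kind = "random", len = len)
}

#' @rdname bridge_layout
#' @param layout a \code{bridge_layout}.
#' @export
layout_length <- function(layout) {
  sum(vapply(layout$segments, `[[`, integer(1) + 0, "len"))
}

# Logical mask of the random positions; fixed template with NA at random.
layout_random_mask <- function(layout) {
  unlist(lapply(layout$segments, function(s) rep(s$kind == "random", s$len)))
}

layout_template <- function(layout) {
  unlist(lapply(layout$segments, function(s) {
    if (s$kind == "fixed") strsplit(s$seq, "")[[1]] else rep(NA_character_, s$len)
  }))
}

#' Default 37-bp bridge layout
#'
#' Three random stretches (9 + 8 + 8 bp) each followed by a 4-bp fixed
#' bridge, totalling 37 bp. Protocol barcodes of this kind interleave short random
#' stretches with fixed linker bases over 37 bp, but the exact arrangement
#' is not public, so this default is one concrete realisation.
#'
#' @return a \code{bridge_layout} of total length 37.
#' @export
default_bridge_layout <- function() {
  bridge_layout(random_segment(9), fixed_segment("GTAC"),
                random_segment(8), fixed_segment("CATG"),
                random_segment(8), fixed_segment("TGCA"))
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' a two-arm (control guide vs perturbation guide) in-utero electroporation
#' experiment: mixed-class clones from ganglionic-eminence progenitors, a
#' fate shift moving probability mass \code{fate_shift_delta} from the PN
#' class to the IN classes in the perturbed arm, batch structure, 37-bp
#' lineage-barcode reads with substitution errors, and a count matrix with
#' a known set of class-informative genes.
#'
#' @param n_progenitors barcoded progenitors (clones) per batch x arm.
#' @param clone_size_law named probability vector over clone sizes (names are
#'   integer sizes >= 1).
#' @param class_probs_control named probability vector over cell classes in
#'   the control arm; a \code{PN} entry is required when
#'   \code{fate_shift_delta > 0}.
#' @param fate_shift_delta probability mass moved from PN to the IN classes
#'   in the perturbed arm; must satisfy
#'   \code{0 <= delta <= class_probs_control["PN"]}.
#' @param fate_shift_to named weights over the classes receiving the shifted
#'   mass (default: equal split over classes whose name starts with "IN").
#' @param n_batches number of batches (embryos/experiments) per arm.
#' @param arm_labels length-2 character: control label first, perturbed second.
#' @param bridge_layout a \code{bridge_layout}; its total length is the
#'   barcode length (default 37).
#' @param per_base_error substitution probability per barcode base per read.
#' @param reads_per_cell barcode reads per cell.
#' @param umis_per_barcode distinct UMIs per cell-barcode molecule pool;
#'   reads sample from this pool, emulating PCR jackpotting.
#' @param quality_model named vector \code{c(mean=, sd=)} of the per-base
#'   Phred score distribution (rounded, clipped to [2, 41]).
#' @param n_genes,n_informative_genes genes in the expression matrix and how
#'   many are class-informative.
#' @param informative_log2fc absolute log2 fold change of informative genes
#'   between PN and IN cells.
#' @param nb_size negative-binomial size (inverse overdispersion) of counts.
#' @param coupling optional list of \code{list(states = c(i, j), factor = f)}
#'   entries; clones are biased so each state pair co-occurs at \code{f}
#'   times its independence rate.
#' @param seed integer root seed; fully determines all generator output.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_progenitors = 100,
                       clone_size_law = c(`1` = 0.35, `2` = 0.25, `3` = 0.16,
                                          `4` = 0.10, `5` = 0.08, `6` = 0.06),
                       class_probs_control = c(mitotic = 0.20, PN = 0.50,
                                               `IN-MGE` = 0.15, `IN-CGE` = 0.15),
                       fate_shift_delta = 0,
                       fate_shift_to = NULL,
                       n_batches = 2,
                       arm_labels = c("gLacZ", "gMeis2"),
                       bridge_layout = default_bridge_layout(),
                       per_base_error = 0.001,
                       reads_per_cell = 10,
                       umis_per_barcode = 3,
                       quality_model = c(mean = 37, sd = 2),
                       n_genes = 1000,
                       n_informative_genes = 50,
                       informative_log2fc = 2,
                       nb_size = 10,
                       coupling = NULL,
                       seed = 1) {
  stop_if_not_prob(clone_size_law, "clone_size_law")
  stop_if_not_prob(class_probs_control, "class_probs_control")
  if (any(as.integer(names(clone_size_law)) < 1L))
    stop("clone sizes must be >= 1")
  if (fate_shift_delta < 0)
    stop("fate_shift_delta must be >= 0")
  if (fate_shift_delta > 0) {
    if (!"PN" %in% names(class_probs_control))
      stop("fate_shift_delta > 0 requires a 'PN' class")
    if (fate_shift_delta > class_probs_control[["PN"]] + 1e-12)
      stop("fate_shift_delta exceeds the control PN probability")
    if (is.null(fate_shift_to)) {
      ins <- grep("^IN", names(class_probs_control), value = TRUE)
      if (!length(ins)) stop("no IN classes to receive the fate shift")
      fate_shift_to <- setNames(rep(1 / length(ins), length(ins)), ins)
    }
    stop_if_not_prob(fate_shift_to, "fate_shift_to")
    if (!all(names(fate_shift_to) %in% names(class_probs_control)))
      stop("fate_shift_to names must be classes in class_probs_control")
  }
  if (length(arm_labels) != 2L || anyDuplicated(arm_labels))
    stop("arm_labels must be two distinct labels")
  if (per_base_error < 0 || per_base_error > 1)
    stop("per_base_error must be in [0, 1]")
  if (!all(c("mean", "sd") %in% names(quality_model)))
    stop("quality_model needs 'mean' and 'sd'")
  cfg <- list(n_progenitors = as.integer(n_progenitors),
              clone_size_law = clone_size_law,
              class_probs_control = class_probs_control,
              fate_shift_delta = fate_shift_delta,
              fate_shift_to = fate_shift_to,
              n_batches = as.integer(n_batches),
              arm_labels = arm_labels,
              bridge_layout = bridge_layout,
              barcode_length = layout_length(bridge_layout),
              per_base_error = per_base_error,
              reads_per_cell = as.integer(reads_per_cell),
              umis_per_barcode = as.integer(umis_per_barcode),
              quality_model = quality_model,
              n_genes = as.integer(n_genes),
              n_informative_genes = as.integer(n_informative_genes),
              informative_log2fc = informative_log2fc,
              nb_size = nb_size,
              coupling = coupling,
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

# Class probabilities of the perturbed arm: delta moved from PN to the
# receiving IN classes.
perturbed_class_probs <- function(config) {
  p <- config$class_probs_control
  d <- config$fate_shift_delta
  if (d > 0) {
    p[["PN"]] <- p[["PN"]] - d
    for (cl in names(config$fate_shift_to))
      p[[cl]] <- p[[cl]] + d * config$fate_shift_to[[cl]]
  }
  p
}
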