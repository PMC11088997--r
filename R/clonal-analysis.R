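#' Class map from cluster annotations to cell classes
#'
#' Inhibitory clusters are merged into broad classes (mitotic, PN, IN) on
#' the basis of their annotation; an optional sub-map splits IN cells by
#' presumed origin (IN-MGE vs IN-CGE).
#'
#' @param classes named character vector: annotation -> class
#'   (mitotic | PN | IN).
#' @param subclasses optional named character vector: annotation -> IN
#'   subclass (IN-MGE | IN-CGE).
#' @return object of class \code{class_map}.
#' @export
class_map <- function(classes, subclasses = NULL) {
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop("classes must be a named vector (annotation -> class)")
  structure(list(classes = classes, subclasses = subclasses),
            class = "class_map")
}

#' @rdname class_map
#' @param path YAML file with a \code{classes} mapping and an optional
#'   \code{subclasses} mapping.
#' @export
read_class_map <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading class maps from YAML requires the yaml package")
  y <- yaml::read_yaml(path)
  class_map(unlist(y$classes),
            if (!is.null(y$subclasses)) unlist(y$subclasses))
}

#' Assign cell classes from cluster annotations
#'
#' Every annotation present in the data must have an entry in the map;
#' unmapped annotations fail loudly, naming them. When a sub-map is given,
#' matching cells additionally receive a \code{subclass} label.
#'
#' @param cell_metadata data.frame with an \code{annotation} column (name
#'   configurable).
#' @param map a \code{\link{class_map}}.
#' @param annotation_col column holding the cluster annotation.
#' @return \code{cell_metadata} with \code{class} (and \code{subclass})
#'   columns added.
#' @export
assign_classes <- function(cell_metadata, map,
                           annotation_col = "annotation") {
  stopifnot(inherits(map, "class_map"))
  ann <- cell_metadata[[annotation_col]]
  if (is.null(ann)) stop("no '", annotation_col, "' column in metadata")
  unmapped <- setdiff(unique(ann), names(map$classes))
  if (length(unmapped))
    stop("annotations missing from the class map: ",
         paste(unmapped, collapse = ", "))
  cell_metadata$class <- unname(map$classes[ann])
  if (!is.null(map$subclasses)) {
    sub <- unname(map$subclasses[ann])
    cell_metadata$subclass <- ifelse(is.na(sub), cell_metadata$class, sub)
  }
  cell_metadata
}

#' Clone-by-class intersection report
#'
#' Maps each clone to the exact set of classes its cells occupy and counts
#' clones per class combination and perturbation arm — the data behind an
#' UpSet plot of clonal fate distributions. Proportions divide each
#' combination's clone count by the total clone count in that arm, so they
#' sum to 1 per arm. Set sizes (cells per class per arm) and per-batch
#' counts are attached as attributes.
#'
#' @param clone_table data.frame with cell_id, clone_id, class, arm, batch.
#' @param multicell_only drop clones of size 1 first.
#' @param class_col column holding the class label (use \code{"subclass"}
#'   for origin-split IN analyses).
#' @return data.frame (combination, arm, count, proportion); combinations
#'   are sorted class names joined by \code{"+"}.
#' @export
intersect_clone_classes <- function(clone_table, multicell_only = FALSE,
                                    class_col = "class") {
  ct <- clone_table
  if (nrow(ct) == 0L)
    return(data.frame(combination = character(0), arm = character(0),
                      count = integer(0), proportion = numeric(0)))
  if (multicell_only) {
    sz <- table(ct$clone_id)
    ct <- ct[ct$clone_id %in% names(sz)[sz >= 2L], , drop = FALSE]
  }
  combo_of <- vapply(split(ct[[class_col]], ct$clone_id),
                     function(x) paste(sort(unique(x)), collapse = "+"),
                     character(1))
  arm_of <- vapply(split(ct$arm, ct$clone_id), function(x) x[1], character(1))
  batch_of <- vapply(split(ct$batch, ct$clone_id), function(x) x[1],
                     character(1))
  tab <- as.data.frame(table(combination = combo_of, arm = arm_of),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0L, , drop = FALSE]
  arm_tot <- tapply(tab$count, tab$arm, sum)
  tab$proportion <- tab$count / as.numeric(arm_tot[tab$arm])
  tab <- tab[order(tab$arm, tab$combination), , drop = FALSE]
  rownames(tab) <- NULL
  set_sizes <- as.data.frame(table(class = ct[[class_col]], arm = ct$arm),
                             stringsAsFactors = FALSE)
  names(set_sizes)[3] <- "n_cells"
  per_batch <- as.data.frame(table(combination = combo_of, arm = arm_of,
                                   batch = batch_of),
                             stringsAsFactors = FALSE)
  names(per_batch)[4] <- "count"
  attr(tab, "set_sizes") <- set_sizes
  attr(tab, "per_batch") <- per_batch[per_batch$count > 0L, , drop = FALSE]
  tab
}

#' Clone-size summary per arm
#'
#' Raw clone sizes plus mean and standard deviation per arm, and per-batch
#' means. With \code{multicell_only}, singleton clones are excluded before
#' summarising. Significance testing between arms is left to standard
#' two-way ANOVA on the returned sizes.
#'
#' @inheritParams intersect_clone_classes
#' @return list with \code{sizes} (clone_id, arm, batch, size),
#'   \code{summary} (arm, n_clones, mean, sd) and \code{per_batch}
#'   (arm, batch, mean).
#' @export
clone_size_summary <- function(clone_table, multicell_only = FALSE) {
  ct <- clone_table
  sizes <- as.data.frame(table(clone_id = ct$clone_id),
                         stringsAsFactors = FALSE)
  names(sizes)[2] <- "size"
  m <- match(sizes$clone_id, ct$clone_id)
  sizes$arm <- ct$arm[m]
  sizes$batch <- ct$batch[m]
  if (multicell_only) sizes <- sizes[sizes$size >= 2L, , drop = FALSE]
  if (nrow(sizes) == 0L)
    return(list(sizes = sizes,
                summary = data.frame(arm = character(0), n_clones = integer(0),
                                     mean = numeric(0), sd = numeric(0)),
                per_batch = data.frame(arm = character(0),
                                       batch = character(0),
                                       mean = numeric(0))))
  smry <- do.call(rbind, lapply(split(sizes, sizes$arm), function(s)
    data.frame(arm = s$arm[1], n_clones = nrow(s), mean = mean(s$size),
               sd = sd(s$size), stringsAsFactors = FALSE)))
  pb <- aggregate(list(mean = sizes$size),
                  by = list(arm = sizes$arm, batch = sizes$batch), FUN = mean)
  rownames(smry) <- NULL
  list(sizes = sizes[, c("clone_id", "arm", "batch", "size")],
       summary = smry, per_batch = pb)
}
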