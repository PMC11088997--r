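#' Build a composition table from per-cell metadata
#'
#' Counts cells per (batch, arm, cell type) over the complete grid of
#' observed types and observed (batch, arm) pairs — absent combinations get
#' an explicit zero — and attaches the per-(batch, arm) totals used as
#' exposure.
#'
#' @param cells data.frame of cells with arm, batch and a type column.
#' @param type_col,arm_col,batch_col column names.
#' @return data.frame (batch, arm, cell_type, count, total).
#' @export
composition_table <- function(cells, type_col = "class", arm_col = "arm",
                              batch_col = "batch") {
  tab <- as.data.frame(table(batch = cells[[batch_col]],
                             arm = cells[[arm_col]],
                             cell_type = cells[[type_col]]),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "count"
  # keep only (batch, arm) pairs that actually occur
  seen <- unique(paste(cells[[batch_col]], cells[[arm_col]], sep = "\r"))
  tab <- tab[paste(tab$batch, tab$arm, sep = "\r") %in% seen, , drop = FALSE]
  tot <- tapply(tab$count, paste(tab$batch, tab$arm, sep = "\r"), sum)
  tab$total <- as.integer(tot[paste(tab$batch, tab$arm, sep = "\r")])
  tab <- tab[order(tab$batch, tab$arm, tab$cell_type), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Differential cell-type composition by Poisson regression
#'
#' For each cell type and each non-control arm, fits
#' \code{count ~ arm + batch + offset(log(total))} with a Poisson family on
#' the (batch, arm) count rows of that type and reports the arm
#' coefficient: the log rate ratio of the type's proportion in the
#' perturbed arm versus control. The exposure offset absorbs arm- and
#' batch-level differences in captured cell numbers. P-values are Wald by
#' default (likelihood-ratio available) and Benjamini-Hochberg adjusted
#' across cell types within each arm comparison.
#'
#' Cell types entirely absent from one arm are not fit on pseudo-data:
#' they are flagged \code{"separation"} with \code{NA} effect and p.
#'
#' @param table composition table from \code{\link{composition_table}}.
#' @param control_label arm serving as the reference.
#' @param test \code{"wald"} (default) or \code{"lrt"}.
#' @return data.frame (cell_type, arm, effect, se, p, q, flag).
#' @export
composition_poisson <- function(table, control_label,
                                test = c("wald", "lrt")) {
  test <- match.arg(test)
  if (!control_label %in% table$arm)
    stop("control label '", control_label, "' not present")
  arms <- setdiff(unique(table$arm), control_label)
  if (!length(arms)) stop("need at least one non-control arm")
  types <- sort(unique(table$cell_type))
  out <- vector("list", 0L)
  for (arm in arms) {
    res <- lapply(types, function(ty) {
      d <- table[table$cell_type == ty & table$arm %in% c(control_label, arm), ,
                 drop = FALSE]
      d$arm_f <- factor(d$arm, levels = c(control_label, arm))
      d$batch_f <- factor(d$batch)
      armsum <- tapply(d$count, d$arm_f, sum)
      if (any(armsum == 0))
        return(data.frame(cell_type = ty, arm = arm, effect = NA_real_,
                          se = NA_real_, p = NA_real_, flag = "separation",
                          stringsAsFactors = FALSE))
      form <- if (nlevels(droplevels(d$batch_f)) > 1L)
        count ~ arm_f + batch_f + offset(log(total)) else
        count ~ arm_f + offset(log(total))
      fit <- glm(form, family = poisson(), data = d)
      co <- summary(fit)$coefficients
      row <- paste0("arm_f", arm)
      eff <- co[row, "Estimate"]
      se <- co[row, "Std. Error"]
      p <- if (test == "wald") co[row, "Pr(>|z|)"] else {
        fit0 <- glm(update(form, . ~ . - arm_f), family = poisson(), data = d)
        stats::pchisq(fit0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
      }
      data.frame(cell_type = ty, arm = arm, effect = eff, se = se, p = p,
                 flag = "", stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$q <- NA_real_
    ok <- res$flag == ""
    res$q[ok] <- p.adjust(res$p[ok], method = "BH")
    out[[length(out) + 1L]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("cell_type", "arm", "effect", "se", "p", "q", "flag")]
}

#' Log10 proportion ratios between arms
#'
#' For each cell type, \code{log10((prop_perturbed + pseudo) /
#' (prop_control + pseudo))} with proportions pooled over batches — the
#' descriptive companion of the Poisson effects.
#'
#' @inheritParams composition_poisson
#' @param pseudo nonnegative pseudo-proportion guarding zero counts.
#' @return data.frame (cell_type, arm, prop_control, prop_perturbed,
#'   log10_ratio).
#' @export
log_ratio_composition <- function(table, control_label, pseudo = 0) {
  stopifnot(pseudo >= 0)
  arms <- setdiff(unique(table$arm), control_label)
  arm_count <- tapply(table$count, list(table$cell_type, table$arm), sum)
  arm_total <- tapply(table$count, table$arm, sum)
  props <- sweep(arm_count, 2L, arm_total[colnames(arm_count)], `/`)
  out <- do.call(rbind, lapply(arms, function(a)
    data.frame(cell_type = rownames(props), arm = a,
               prop_control = props[, control_label],
               prop_perturbed = props[, a],
               log10_ratio = log10((props[, a] + pseudo) /
                                   (props[, control_label] + pseudo)),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Perturbation effects on gene-module scores
#'
#' For each precomputed module score and each non-control arm, fits a linear
#' model \code{score ~ arm + batch + n_genes} on the control and perturbed
#' cells and reports the arm coefficient — how much the module score in
#' perturbed cells deviates from control after accounting for batch and
#' per-cell gene counts. P-values are Bonferroni-adjusted across all
#' module-by-arm tests. Modules with constant scores in a comparison are
#' flagged degenerate with effect 0 and p 1.
#'
#' @param scores long data.frame (cell_id, module, score).
#' @param metadata data.frame (cell_id, arm, batch, n_genes).
#' @param control_label reference arm.
#' @return data.frame (module, arm, effect, se, p, p_adj, flag).
#' @export
module_score_effects <- function(scores, metadata, control_label) {
  stopifnot(all(c("cell_id", "module", "score") %in% names(scores)),
            all(c("cell_id", "arm", "batch", "n_genes") %in% names(metadata)))
  m <- match(scores$cell_id, metadata$cell_id)
  if (anyNA(m)) stop("score cells missing from metadata")
  scores$arm <- metadata$arm[m]
  scores$batch <- metadata$batch[m]
  scores$n_genes <- metadata$n_genes[m]
  arms <- setdiff(unique(scores$arm), control_label)
  mods <- sort(unique(scores$module))
  out <- vector("list", 0L)
  for (arm in arms) for (mod in mods) {
    d <- scores[scores$module == mod & scores$arm %in% c(control_label, arm), ,
                drop = FALSE]
    d$arm_f <- factor(d$arm, levels = c(control_label, arm))
    if (var(d$score) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        module = mod, arm = arm, effect = 0, se = NA_real_, p = 1,
        flag = "degenerate", stringsAsFactors = FALSE)
      next
    }
    form <- if (length(unique(d$batch)) > 1L)
      score ~ arm_f + factor(batch) + n_genes else score ~ arm_f + n_genes
    fit <- lm(form, data = d)
    co <- summary(fit)$coefficients
    row <- paste0("arm_f", arm)
    out[[length(out) + 1L]] <- data.frame(
      module = mod, arm = arm, effect = co[row, "Estimate"],
      se = co[row, "Std. Error"], p = co[row, "Pr(>|t|)"], flag = "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out$p_adj <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out[, c("module", "arm", "effect", "se", "p", "p_adj", "flag")]
}
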