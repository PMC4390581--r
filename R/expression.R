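#' Read a control/stress expression table
#'
#' Tab-separated with header `gene_id, control, stress`; levels are
#' arbitrary positive units (the pipeline consumes pre-summarised array or
#' qPCR levels, never raw probe data). Zero or negative levels are an error
#' at load time.
#'
#' @param path TSV file.
#' @return data.frame with columns gene_id, control, stress.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  stopifnot(all(c("gene_id", "control", "stress") %in% names(df)))
  df$gene_id <- as.character(df$gene_id)
  df$control <- as.numeric(df$control)
  df$stress <- as.numeric(df$stress)
  check_levels(df)
  df
}

check_levels <- function(df) {
  bad <- !is.finite(df$control) | !is.finite(df$stress) |
    df$control <= 0 | df$stress <= 0
  if (any(bad)) {
    stop("non-positive expression level(s) for gene(s): ",
         paste(df$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Classify regulation from control/stress levels
#'
#' Fold change is stress/control. Thresholds are inclusive ("at least"): a
#' gene is `up` when fold change >= `up_threshold` (default 2), `down` when
#' fold change <= 1/`down_threshold` (default 1.5), otherwise `unchanged`.
#' The classification is scale-invariant in the level units.
#'
#' @param records data.frame with columns gene_id, control, stress.
#' @param up_threshold,down_threshold fold-change thresholds, both > 1.
#' @return data.frame with columns gene_id, fold_change, label (factor with
#'   levels up/down/unchanged), up_threshold, down_threshold.
#' @export
#' @examples
#' classify_regulation(data.frame(gene_id = "Ldh", control = 1, stress = 2))
classify_regulation <- function(records, up_threshold = 2.0,
                                down_threshold = 1.5) {
  stopifnot(up_threshold > 1, down_threshold > 1)
  check_levels(records)
  fc <- records$stress / records$control
  label <- ifelse(fc >= up_threshold, "up",
                  ifelse(fc <= 1 / down_threshold, "down", "unchanged"))
  data.frame(gene_id = records$gene_id, fold_change = fc,
             label = factor(label, levels = c("up", "down", "unchanged")),
             up_threshold = up_threshold, down_threshold = down_threshold,
             stringsAsFactors = FALSE)
}

#' Read a qPCR Ct table
#'
#' Tab-separated with header `gene_id, condition, replicate, ct`.
#'
#' @param path TSV file.
#' @return data.frame with those four columns; ct must be finite.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  stopifnot(all(c("gene_id", "condition", "replicate", "ct") %in% names(df)))
  df$gene_id <- as.character(df$gene_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.character(df$replicate)
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct))) stop("non-finite Ct value(s)", call. = FALSE)
  df
}

#' Reference-normalised relative expression from Ct values
#'
#' Classic efficiency^(Ct_ref - Ct_target) relative quantification against a
#' housekeeping reference (RpL19 in the motivating experiments). Within each
#' condition, target and reference replicates are paired by replicate id
#' when the id sets match; otherwise each target replicate is normalised by
#' the reference-condition mean Ct. Per-replicate levels are summarised on
#' the log scale: the reported mean is the geometric mean and the dispersion
#' is the SE of the log-levels propagated to the linear scale (delta
#' method). Single-replicate conditions report dispersion 0 with a warning.
#'
#' @param target QpcrMeasurement rows (one gene) for the gene of interest.
#' @param reference rows for the reference gene; must cover every target
#'   condition.
#' @param efficiency amplification efficiency, in (1, 2]; 2 = perfect
#'   doubling per cycle.
#' @param calibrate_to optional condition name; all conditions are divided
#'   by that condition's mean level (so the calibrator becomes 1).
#' @return data.frame with columns gene_id, condition, mean_level,
#'   dispersion, n_replicates.
#' @export
qpcr_relative <- function(target, reference, efficiency = 2.0,
                          calibrate_to = NULL) {
  stopifnot(efficiency > 1, efficiency <= 2)
  conds <- unique(target$condition)
  missing_ref <- setdiff(conds, unique(reference$condition))
  if (length(missing_ref) > 0L) {
    stop("reference gene has no measurements for condition(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  gene <- unique(target$gene_id)
  if (length(gene) != 1L) {
    stop("qpcr_relative expects measurements for exactly one target gene",
         call. = FALSE)
  }
  out <- lapply(conds, function(cond) {
    tg <- target[target$condition == cond, ]
    rf <- reference[reference$condition == cond, ]
    if (setequal(tg$replicate, rf$replicate) &&
        !anyDuplicated(tg$replicate) && !anyDuplicated(rf$replicate)) {
      rf_ct <- rf$ct[match(tg$replicate, rf$replicate)]
    } else {
      rf_ct <- rep(mean(rf$ct), nrow(tg))
    }
    log_levels <- (rf_ct - tg$ct) * log(efficiency)  # natural-log scale
    n <- length(log_levels)
    mean_log <- mean(log_levels)
    se_log <- if (n > 1L) stats::sd(log_levels) / sqrt(n) else {
      warning(sprintf("single replicate for %s/%s: dispersion reported as 0",
                      gene, cond), call. = FALSE)
      0
    }
    data.frame(gene_id = gene, condition = cond,
               mean_level = exp(mean_log),
               dispersion = exp(mean_log) * se_log,
               n_replicates = n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (!is.null(calibrate_to)) {
    if (!calibrate_to %in% res$condition) {
      stop("calibrate_to condition not present: ", calibrate_to, call. = FALSE)
    }
    cal <- res$mean_level[res$condition == calibrate_to]
    res$mean_level <- res$mean_level / cal
    res$dispersion <- res$dispersion / cal
  }
  res
}

#' Paired two-sided Student's t-test
#'
#' Implemented from the formula: t = mean(d) / (sd(d)/sqrt(n)) with
#' d = x - y and df = n - 1; p from the t distribution. Degenerate inputs
#' (zero variance of the differences) are flagged: p = 1 when the mean
#' difference is also zero, p = 0 otherwise.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with elements t, p, df, degenerate (logical).
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1L, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L, degenerate = TRUE))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), df = n - 1L,
       degenerate = FALSE)
}
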