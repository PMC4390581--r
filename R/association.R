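#' Cross-tabulate motif presence against regulation class
#'
#' Partitions genes into the 2x2 table (a, b, c, d) = (up & site,
#' up & no-site, not-up & site, not-up & no-site), where "up" means
#' `label == positive_label`. This formalises "how many up-regulated genes
#' carry at least one binding site" as a contingency table amenable to an
#' exact test.
#'
#' @param calls regulation-call data.frame from [classify_regulation()].
#' @param has_site named logical vector (gene_id -> site present), e.g. from
#'   [scan_promoters()].
#' @param positive_label the regulation label treated as positive.
#' @return object of class `contingency_result` with counts a, b, c, d
#'   (odds ratio and p are filled in by [fisher_exact_two_sided()], which
#'   this function calls).
#' @export
build_contingency <- function(calls, has_site, positive_label = "up") {
  missing <- setdiff(calls$gene_id, names(has_site))
  if (length(missing) > 0L) {
    stop("gene(s) missing from has_site: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pos <- calls$label == positive_label
  site <- unname(has_site[calls$gene_id])
  a <- sum(pos & site); b <- sum(pos & !site)
  c <- sum(!pos & site); d <- sum(!pos & !site)
  res <- fisher_exact_two_sided(a, b, c, d)
  res$positive_label <- positive_label
  res
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value follows the probability-ordering convention: the
#' sum, over all tables with the observed margins, of hypergeometric
#' probabilities at most that of the observed table (relative tolerance
#' 1e-7 for ties). Computed by explicit enumeration over the feasible range
#' of cell `a` in log space. The odds ratio is the sample (unconditional)
#' (a*d)/(b*c), +Inf when b*c = 0 with a*d > 0, and flagged undefined when
#' any margin is zero (in which case p = 1).
#'
#' @param a,b,c,d non-negative integer counts (rows: up / not-up; columns:
#'   site / no-site).
#' @return object of class `contingency_result`: a, b, c, d, odds_ratio,
#'   p_two_sided, method, degenerate.
#' @export
#' @examples
#' fisher_exact_two_sided(6, 1, 1, 3)  # p = 29/330
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  N <- r1 + r2
  res <- structure(list(a = a, b = b, c = c, d = d, odds_ratio = NA_real_,
                        p_two_sided = 1, method = "fisher.exact.enumeration",
                        degenerate = FALSE),
                   class = "contingency_result")
  if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) {
    res$degenerate <- TRUE
    return(res)
  }
  res$odds_ratio <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  # log hypergeometric pmf for cell a = k, margins fixed
  ks <- max(0L, r1 - c2):min(r1, c1)
  logp <- lchoose(c1, ks) + lchoose(c2, r1 - ks) - lchoose(N, r1)
  log_obs <- lchoose(c1, a) + lchoose(c2, b) - lchoose(N, r1)
  keep <- logp <= log_obs + log1p(1e-7)
  res$p_two_sided <- min(1, sum(exp(logp[keep])))
  res
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.contingency_result <- function(x, ...) {
  or <- if (is.na(x$odds_ratio)) "undefined" else
    formatC(x$odds_ratio, digits = 4, format = "g")
  c("Motif presence vs. regulation (2x2)",
    sprintf("             site  no-site"),
    sprintf("  up         %4d  %7d", x$a, x$b),
    sprintf("  not-up     %4d  %7d", x$c, x$d),
    sprintf("  odds ratio = %s", or),
    sprintf("  two-sided exact p = %.6g%s", x$p_two_sided,
            if (isTRUE(x$degenerate)) "  (degenerate margins)" else ""))
}

#' One-line TSV serialisation of a contingency result
#' @param x a `contingency_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contingency_tsv <- function(x, path) {
  df <- data.frame(a = x$a, b = x$b, c = x$c, d = x$d,
                   odds_ratio = x$odds_ratio, p_two_sided = x$p_two_sided,
                   method = x$method)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
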