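# Normalization and per-gene moderated statistics: quantile normalization,
# Tukey median-polish probe summarization, two-group / paired contrasts and
# empirical-Bayes variance moderation (prior estimated by moment matching on
# log residual variances).

#' Quantile-normalize an expression matrix
#'
#' Forces every column onto the common distribution given by the row-wise
#' mean of the column-sorted input. Ties within a column receive the mean of
#' their quantile targets, so tied values stay tied.
#'
#' @param values Numeric matrix, all finite, >= 2 columns (a single column
#'   is returned unchanged with a warning).
#' @return Matrix of the same shape with equalized column distributions.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) dg_stop("Matrix must be all finite.")
  if (ncol(values) < 2) {
    dg_warn("Single-column matrix: quantile normalization is the identity.")
    return(values)
  }
  target <- rowMeans(apply(values, 2, sort))
  out <- apply(values, 2, function(col) {
    o <- order(col)
    v <- col[o]
    grp <- cumsum(c(TRUE, v[-1] != v[-length(v)]))
    tied_target <- stats::ave(target, grp)
    res <- numeric(length(col))
    res[o] <- tied_target
    res
  })
  dimnames(out) <- dimnames(values)
  out
}

#' Summarize probe-level values to gene level by median polish
#'
#' Fits an additive probe + sample decomposition per gene block with Tukey
#' median polish; the gene value for each sample is the fitted overall
#' effect plus that sample's column effect. Robust to a minority of outlier
#' probes, unlike a column mean.
#'
#' @param probe_values Numeric matrix, rows = probes.
#' @param probe_to_gene Named character vector or two-column data frame
#'   (`probe`, `gene`) mapping every probe to exactly one gene.
#' @param max_iter Maximum polish iterations.
#' @param tol Convergence threshold on the residual row/column medians.
#' @return Gene-level matrix (rows sorted by gene id); genes with zero
#'   probes are absent.
#' @export
median_polish_summarize <- function(probe_values, probe_to_gene,
                                    max_iter = 10, tol = 0.01) {
  probe_values <- as.matrix(probe_values)
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(norm_gene_id(probe_to_gene[[2]]),
                           as.character(probe_to_gene[[1]]))
  } else {
    map <- stats::setNames(norm_gene_id(probe_to_gene),
                           names(probe_to_gene))
  }
  probes <- rownames(probe_values)
  missing <- setdiff(probes, names(map))
  if (length(missing) > 0) {
    dg_stop(sprintf("Probe(s) without a gene mapping: %s",
                    paste(head(missing, 3), collapse = ", ")))
  }
  genes <- sort(unique(map[probes]))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(probe_values),
                dimnames = list(genes, colnames(probe_values)))
  for (g in genes) {
    block <- probe_values[probes[map[probes] == g], , drop = FALSE]
    if (nrow(block) == 1) {
      out[g, ] <- block[1, ]
    } else {
      mp <- suppressWarnings(
        stats::medpolish(block, eps = tol, maxiter = max_iter,
                         trace.iter = FALSE)
      )
      out[g, ] <- mp$overall + mp$col
    }
  }
  out
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(0, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

#' Fit a case-versus-control contrast
#'
#' Computes, per gene, the log2 fold change (case minus control), residual
#' variance, residual degrees of freedom and the unscaled variance
#' multiplier of the effect. Two designs are supported: an independent
#' two-group comparison (pooled variance, `df = n1 + n2 - 2`,
#' `v = 1/n1 + 1/n2`) and a paired design via the sample sheet's `pair`
#' column (`beta` = mean paired difference, `df = n_pairs - 1`,
#' `v = 1/n_pairs`).
#'
#' @param study An [expression_study()].
#' @param stage_filter Optional stage label; keeps only that stage's
#'   samples. `NULL` uses all samples (the stage-agnostic "diagnosis"
#'   contrast).
#' @param paired Force paired/unpaired; defaults to paired when the sheet
#'   has a `pair` column.
#' @return A tibble of class `contrast_result` with columns `gene`, `beta`,
#'   `s2`, `df_resid`, `v`, and attributes `n_case`, `n_control`,
#'   `contrast`.
#' @export
fit_contrast <- function(study, stage_filter = NULL, paired = NULL) {
  sheet <- study$sample_sheet
  if (is.null(paired)) paired <- "pair" %in% names(sheet)
  if (!is.null(stage_filter)) {
    sheet <- filter(sheet, .data$stage == stage_filter)
  }
  n_case <- sum(sheet$condition == "case")
  n_control <- sum(sheet$condition == "control")
  if (n_case == 0 || n_control == 0) {
    dg_stop(sprintf(
      "Contrast '%s' leaves an empty arm (%d case / %d control).",
      stage_filter %||% "diagnosis", n_case, n_control
    ))
  }
  if (n_case < 2 || n_control < 2) {
    dg_stop("Need >= 2 samples per arm after filtering.")
  }
  x <- study$values[, sheet$sample, drop = FALSE]

  if (paired) {
    if (!"pair" %in% names(sheet)) {
      dg_stop("Paired analysis requested but the sheet has no 'pair' column.")
    }
    cs <- filter(sheet, .data$condition == "case")
    ct <- filter(sheet, .data$condition == "control")
    common <- intersect(cs$pair, ct$pair)
    if (length(common) < 2) dg_stop("Need >= 2 complete pairs.")
    cs <- cs[match(common, cs$pair), ]
    ct <- ct[match(common, ct$pair), ]
    diffs <- x[, cs$sample, drop = FALSE] - x[, ct$sample, drop = FALSE]
    beta <- rowMeans(diffs)
    s2 <- row_vars(diffs)
    df_resid <- length(common) - 1
    v <- 1 / length(common)
  } else {
    xc <- x[, sheet$sample[sheet$condition == "case"], drop = FALSE]
    xn <- x[, sheet$sample[sheet$condition == "control"], drop = FALSE]
    beta <- rowMeans(xc) - rowMeans(xn)
    ss <- row_vars(xc) * (ncol(xc) - 1) + row_vars(xn) * (ncol(xn) - 1)
    df_resid <- ncol(xc) + ncol(xn) - 2
    s2 <- ss / df_resid
    v <- 1 / ncol(xc) + 1 / ncol(xn)
  }

  out <- tibble(
    gene = rownames(x),
    beta = unname(beta),
    s2 = unname(s2),
    df_resid = df_resid,
    v = v
  )
  attr(out, "contrast") <- stage_filter %||% "diagnosis"
  attr(out, "n_case") <- n_case
  attr(out, "n_control") <- n_control
  attr(out, "paired") <- paired
  class(out) <- c("contrast_result", class(out))
  out
}

# Invert the (monotone decreasing) trigamma function by bisection on a
# bracket wide enough for any variance that arises in practice.
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    lo <- 1e-8
    hi <- 1e8
    if (trigamma(lo) < yy) return(lo)
    if (trigamma(hi) > yy) return(hi)
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (trigamma(mid) > yy) lo <- mid else hi <- mid
      if (hi / lo < 1 + 1e-12) break
    }
    sqrt(lo * hi)
  }, numeric(1))
}

#' Empirical-Bayes moderation of contrast variances
#'
#' Shrinks each gene's residual variance toward an ensemble prior and forms
#' moderated t-statistics. The prior (`d0`, `s0^2`) is estimated by moment
#' matching on `z_g = log(s2_g)` against the scaled-F marginal implied by an
#' inverse-chi-square prior: the mean and variance of `z` are matched using
#' digamma/trigamma identities, with the trigamma inversion done by monotone
#' bisection. When the observed spread of `z` is no larger than the
#' within-gene chi-square contribution, the prior degrees of freedom are
#' infinite and every posterior variance equals `s0^2`. The posterior
#' variance is `s2_post = (d0*s0^2 + df*s2) / (d0 + df)`, the moderated t is
#' `beta / sqrt(s2_post * v)` and two-sided p-values use a t distribution on
#' `d0 + df` degrees of freedom (capped at 1e6).
#'
#' @param fit A [fit_contrast()] result with >= 10 genes.
#' @param prior_df,prior_var Optional overrides for the estimated prior.
#' @return An object of class `moderated_stats`: list with per-gene tibble
#'   `$table` (`gene`, `lfc`, `t_mod`, `p`, `s2`, `s2_post`, `df_total`) and
#'   scalars `$d0`, `$s0_2`.
#' @export
ebayes_moderate <- function(fit, prior_df = NULL, prior_var = NULL) {
  if (nrow(fit) < 10 && is.null(prior_df)) {
    dg_stop("Prior estimation needs an ensemble of >= 10 genes.")
  }
  if (any(fit$df_resid <= 0)) dg_stop("All df_resid must be > 0.")
  d <- fit$df_resid
  s2 <- fit$s2

  if (is.null(prior_df)) {
    ok <- s2 > 0
    if (!any(ok)) dg_stop("All residual variances are zero.")
    z <- log(s2[ok])
    e <- z - digamma(d[ok] / 2) + log(d[ok] / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(d[ok] / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_2 <- exp(emean)
    }
  } else {
    d0 <- prior_df
    s0_2 <- prior_var %||% mean(s2)
  }

  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  df_total <- pmin(d0 + d, 1e6)
  t_mod <- fit$beta / sqrt(s2_post * fit$v)
  p <- 2 * pt(-abs(t_mod), df = df_total)

  structure(list(
    table = tibble(
      gene = fit$gene,
      lfc = fit$beta,
      t_mod = t_mod,
      p = p,
      s2 = s2,
      s2_post = s2_post,
      df_total = df_total
    ),
    d0 = d0,
    s0_2 = s0_2,
    contrast = attr(fit, "contrast") %||% "contrast"
  ), class = "moderated_stats")
}

#' @export
print.moderated_stats <- function(x, ...) {
  cat(sprintf(
    "<moderated_stats '%s'> %d genes; prior d0 = %s, s0^2 = %.4g\n",
    x$contrast, nrow(x$table),
    if (is.infinite(x$d0)) "Inf" else sprintf("%.3g", x$d0), x$s0_2
  ))
  invisible(x)
}

#' All case/control contrasts of a study, moderated
#'
#' For a multi-stage study this is one contrast per stage plus the
#' stage-agnostic "diagnosis" contrast (all cases versus all controls); a
#' single-stage study yields only the diagnosis contrast. Paired analysis is
#' used whenever the sample sheet has a `pair` column.
#'
#' @param study An [expression_study()].
#' @return Named list of `moderated_stats`.
#' @export
study_contrasts <- function(study) {
  stages <- unique(study$sample_sheet$stage)
  fits <- list(diagnosis = ebayes_moderate(fit_contrast(study)))
  if (length(stages) > 1) {
    for (st in stages) {
      fits[[st]] <- ebayes_moderate(fit_contrast(study, stage_filter = st))
    }
  }
  fits
}
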