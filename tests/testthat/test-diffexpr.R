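# Normalization, summarization, contrasts and empirical-Bayes moderation.

test_that("quantile normalization matches hand-computed targets", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  y <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(y), y)

  # ties receive the mean of their quantile targets
  z <- cbind(a = c(1, 1, 5), b = c(2, 4, 6))
  qz <- quantile_normalize(z)
  expect_equal(qz[1, "a"], qz[2, "a"])
  expect_equal(unname(qz[1, "a"]), mean(c(mean(c(1, 2)), mean(c(1, 4)))))
})

test_that("quantile normalization equalizes columns, is idempotent, matches limma", {
  set.seed(1)
  x <- matrix(rnorm(300), 50, 6)
  qn <- quantile_normalize(x)
  cm <- colMeans(qn)
  expect_lt(max(cm) - min(cm), 1e-9)
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-9)
  expect_equal(qn, limma::normalizeQuantiles(x), tolerance = 1e-9)
  expect_warning(quantile_normalize(x[, 1, drop = FALSE]), "Single-column")
})

test_that("median polish summarization is exact on additive blocks and robust", {
  # one probe per gene: identity
  x <- matrix(rnorm(8), 2, 4, dimnames = list(c("p1", "p2"), NULL))
  out <- median_polish_summarize(x, c(p1 = "g1", p2 = "g2"))
  expect_equal(unname(out["G1", ]), unname(x["p1", ]))

  # pure probe-effect + sample-effect block: zero residuals, exact recovery
  probe_eff <- c(0, 1, -1)
  samp_eff <- c(0, 2, 4, 6)
  block <- outer(probe_eff, samp_eff, `+`) + 5
  rownames(block) <- paste0("p", 1:3)
  out2 <- median_polish_summarize(block, setNames(rep("g", 3),
                                                  rownames(block)),
                                  tol = 1e-9, max_iter = 50)
  expect_equal(unname(out2["G", ]), 5 + samp_eff, tolerance = 1e-8)

  # a probe corrupted in a few samples hurts the mean more than the polish
  set.seed(2)
  truth <- rnorm(6, 8)
  outlier <- truth
  outlier[c(2, 5)] <- outlier[c(2, 5)] + 6   # sample-specific corruption
  block3 <- rbind(matrix(rep(truth, 4), 4, 6, byrow = TRUE) +
                    rnorm(24, 0, 0.05),
                  outlier)
  rownames(block3) <- paste0("p", 1:5)
  polished <- median_polish_summarize(
    block3, setNames(rep("g", 5), rownames(block3))
  )["G", ]
  mean_sum <- colMeans(block3)
  centered <- function(v) v - mean(v)
  expect_lt(sum((centered(polished) - centered(truth))^2),
            sum((centered(mean_sum) - centered(truth))^2))
})

test_that("two-group contrasts match hand-computed pooled statistics", {
  vals <- matrix(c(1, 2, 3, 4), 1, 4,
                 dimnames = list("G1", paste0("s", 1:4)))
  sheet <- tibble::tibble(sample = paste0("s", 1:4),
                          condition = c("case", "case",
                                        "control", "control"),
                          stage = "mid")
  fit <- fit_contrast(expression_study(vals, sheet))
  expect_equal(fit$beta, -2)
  expect_equal(fit$s2, 0.5)
  expect_equal(fit$df_resid, 2)
  expect_equal(fit$v, 1)

  # identical arms: beta 0, variance 0
  vals2 <- matrix(c(5, 5, 5, 5), 1, 4, dimnames = dimnames(vals))
  fit2 <- fit_contrast(expression_study(vals2, sheet))
  expect_equal(fit2$beta, 0)
  expect_equal(fit2$s2, 0)
})

test_that("stage filtering and paired designs follow the sheet", {
  genes <- sprintf("G%03d", 1:40)
  st <- simulate_expression(
    genes,
    tibble::tibble(stage = c("incipient", "severe"),
                   n_case = c(3, 4), n_control = c(3, 4)),
    rng_seed = 5
  )
  fit <- fit_contrast(st, stage_filter = "severe")
  expect_equal(attr(fit, "n_case") + attr(fit, "n_control"),
               sum(st$sample_sheet$stage == "severe"))
  expect_error(fit_contrast(st, stage_filter = "late"), "late")

  stp <- simulate_expression(
    genes, tibble::tibble(stage = "mid", n_case = 6, n_control = 6),
    paired = TRUE, rng_seed = 6
  )
  fitp <- fit_contrast(stp)
  expect_true(attr(fitp, "paired"))
  expect_equal(unique(fitp$df_resid), 5)
  expect_equal(unique(fitp$v), 1 / 6)
})

test_that("eBayes limits behave: infinite prior ranks by |beta|, zero prior is ordinary t", {
  genes <- sprintf("G%03d", 1:60)
  st <- simulate_expression(
    genes, tibble::tibble(stage = "mid", n_case = 5, n_control = 5),
    de_genes = genes[1:10], effect_size = 1, rng_seed = 7
  )
  fit <- fit_contrast(st)

  inf <- ebayes_moderate(fit, prior_df = Inf, prior_var = 1)
  expect_equal(order(-abs(tidy(inf)$t_mod)), order(-abs(fit$beta)))
  expect_true(all(tidy(inf)$s2_post == 1))

  zero <- ebayes_moderate(fit, prior_df = 0)
  t_ord <- fit$beta / sqrt(fit$s2 * fit$v)
  expect_equal(tidy(zero)$t_mod, t_ord)
})

test_that("identical residual variances trigger the infinite-prior branch", {
  fit <- tibble::tibble(gene = sprintf("G%02d", 1:20),
                        beta = rnorm(20), s2 = 2, df_resid = 4, v = 0.5)
  class(fit) <- c("contrast_result", class(fit))
  mod <- ebayes_moderate(fit)
  expect_true(is.infinite(mod$d0))
  expect_true(all(mod$table$s2_post == mod$s0_2))
})

test_that("the moment-matching prior recovers planted (d0 = 4, s0^2 = 1)", {
  recovered <- vapply(1:10, function(seed) {
    set.seed(seed)
    n_g <- 2000
    d_g <- 4
    sigma2 <- 1 * 4 / stats::rchisq(n_g, df = 4)   # inverse-chi-square prior
    s2 <- sigma2 * stats::rchisq(n_g, df = d_g) / d_g
    fit <- tibble::tibble(gene = sprintf("G%04d", 1:n_g),
                          beta = rnorm(n_g, 0, sqrt(sigma2 * 0.2)),
                          s2 = s2, df_resid = d_g, v = 0.2)
    class(fit) <- c("contrast_result", class(fit))
    ebayes_moderate(fit)$d0
  }, numeric(1))
  expect_true(all(recovered >= 2.5 & recovered <= 6))
})

test_that("moderation agrees with the reference empirical-Bayes implementation", {
  set.seed(12)
  n_g <- 500
  d_g <- 6
  s2 <- 0.8 * stats::rchisq(n_g, d_g) / d_g * (3 / stats::rchisq(n_g, 3) * 3)
  fit <- tibble::tibble(gene = sprintf("G%04d", 1:n_g),
                        beta = rnorm(n_g), s2 = s2, df_resid = d_g,
                        v = 0.25)
  class(fit) <- c("contrast_result", class(fit))
  mod <- ebayes_moderate(fit)
  ref <- limma::squeezeVar(fit$s2, df = d_g)
  expect_equal(mod$d0, ref$df.prior, tolerance = 1e-4)
  expect_equal(mod$s0_2, ref$var.prior, tolerance = 1e-4)
  expect_equal(mod$table$s2_post, ref$var.post, tolerance = 1e-6)
})

test_that("shrinkage is monotone around the prior variance", {
  set.seed(13)
  fit <- tibble::tibble(gene = sprintf("G%03d", 1:200),
                        beta = rnorm(200),
                        s2 = stats::rchisq(200, 4) / 4,
                        df_resid = 4, v = 0.5)
  class(fit) <- c("contrast_result", class(fit))
  mod <- ebayes_moderate(fit)
  tab <- mod$table
  below <- tab$s2 < mod$s0_2
  expect_true(all(tab$s2_post[below] > tab$s2[below]))
  expect_true(all(tab$s2_post[!below] <= tab$s2[!below]))
})

test_that("moderated p-values are uniform under the null", {
  genes <- sprintf("G%04d", 1:800)
  st <- simulate_expression(
    genes, tibble::tibble(stage = "mid", n_case = 6, n_control = 6),
    effect_size = 0, sigma = 1, batch_shift = 0, rng_seed = 30
  )
  p <- tidy(ebayes_moderate(fit_contrast(st)))$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("study_contrasts produces one fit per stage plus diagnosis", {
  genes <- sprintf("G%03d", 1:30)
  st <- simulate_expression(
    genes,
    tibble::tibble(stage = c("incipient", "moderate", "severe"),
                   n_case = 3, n_control = 3),
    rng_seed = 9
  )
  cs <- study_contrasts(st)
  expect_setequal(names(cs),
                  c("diagnosis", "incipient", "moderate", "severe"))
})
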