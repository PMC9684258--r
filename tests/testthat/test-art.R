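test_that("constant responses align to full midrank ties", {
  d <- expand.grid(subject = 1:6, condition = c("pre", "post"),
                   template = c("A", "B"))
  d$value <- 5
  r <- art_align_and_rank(d, "value", c("condition", "template"), "condition")
  expect_true(all(r == (nrow(d) + 1) / 2))
})

test_that("single-factor ART equals the plain rank-transform ANOVA", {
  set.seed(61)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 10),
                  value = rnorm(30) + rep(c(0, 0.5, 1), each = 10))
  a <- art_anova(d, "value", "g")
  # direct route: ANOVA on midranks of the raw response
  ref <- anova(lm(rank(d$value) ~ d$g))
  expect_equal(a$table$F, ref$`F value`[1])
  expect_equal(a$table$p, ref$`Pr(>F)`[1])
})

test_that("alignment removes non-target effects exactly", {
  set.seed(62)
  d <- expand.grid(subject = 1:9, condition = c("pre", "post"),
                   template = c("A", "B", "C"))
  d$value <- rnorm(nrow(d)) + 2 * (d$condition == "post") +
    as.numeric(d$template)
  for (eff in list("condition", "template", c("condition", "template"))) {
    # aligned response (pre-rank) computed independently from cell means
    y <- d$value
    cm <- stats::ave(y, d[c("condition", "template")])
    est <- switch(paste(eff, collapse = ":"),
                  "condition" = stats::ave(y, d["condition"]) - mean(y),
                  "template" = stats::ave(y, d["template"]) - mean(y),
                  "condition:template" = cm - stats::ave(y, d["condition"]) -
                    stats::ave(y, d["template"]) + mean(y))
    aligned <- y - cm + est
    # the aligned response must sum to zero within every level of each
    # non-target effect
    others <- setdiff(c("condition", "template"), eff)
    for (f in others) {
      sums <- tapply(aligned, d[[f]], sum)
      expect_true(all(abs(sums) < 1e-9))
    }
    # and the package's ranks must be the ranks of this aligned response
    expect_equal(art_align_and_rank(d, "value",
                                    c("condition", "template"), eff),
                 rank(aligned))
  }
})

test_that("denominator dfs reproduce the published design shapes", {
  set.seed(63)
  d <- null_metrics_table()
  a <- art_anova(d, "value", c("condition", "template"))
  expect_equal(a$table$df2, rep(208, 3))
  expect_equal(a$table$df1, c(1, 3, 3))
  a3 <- art_anova(d, "value", c("condition", "template", "side"))
  expect_true(all(a3$table$df2 == 200))
  dtr <- null_metrics_table(levels = paste0("P", 1:6), factor_name = "pair")
  b <- art_anova(dtr, "value", c("condition", "pair"))
  expect_equal(b$table$df2, rep(312, 3))
  expect_equal(b$table$df1, c(1, 5, 5))
  b3 <- art_anova(dtr, "value", c("condition", "pair", "side"))
  expect_true(all(b3$table$df2 == 300))
})

test_that("single-factor ART is invariant to rank-preserving transforms", {
  # alignment for a sole factor reduces to a grand-mean shift, so the ranks
  # (and hence F) depend on the response only through its ordering
  set.seed(64)
  d <- data.frame(g = rep(c("a", "b", "c", "d"), each = 12),
                  value = rnorm(48) + rep(c(0, 0.3, 0.6, 0.9), each = 12))
  a1 <- art_anova(d, "value", "g")
  d$value <- exp(d$value)
  a2 <- art_anova(d, "value", "g")
  expect_equal(a1$table$F, a2$table$F)
})

test_that("missing cells are reported", {
  d <- null_metrics_table(n_subjects = 4)
  d <- d[!(d$condition == "post" & d$template == "D"), ]
  expect_error(art_anova(d, "value", c("condition", "template")), "post:D")
})

test_that("planted condition effects are detected with high power", {
  set.seed(65)
  hits <- replicate(50, {
    d <- null_metrics_table(bd_shift = 0.2)
    art_anova(d, "value", c("condition", "template"),
              effects = list("condition"))$table$p < 0.01
  })
  expect_gte(mean(hits), 0.9)
})

test_that("ART-C contrasts isolate the shifted templates", {
  set.seed(66)
  d <- null_metrics_table(bd_shift = 0.2)
  ct <- art_c_contrasts(d, "value", c("condition", "template"),
                        c("condition", "template"),
                        pairs = lapply(c("A", "B", "C", "D"), function(t) {
                          c(paste0("pre:", t), paste0("post:", t))
                        }))
  expect_equal(nrow(ct), 4L)
  sig <- ct$p_adj < 0.05
  expect_true(all(sig[c(2, 4)]))   # B and D shifted
  expect_false(any(sig[c(1, 3)]))
  expect_true(all(ct$p_adj >= ct$p_raw))
  expect_true(all(ct$p_adj <= 1))
  expect_error(art_c_contrasts(d, "value", c("condition", "template"),
                               "condition", pairs = list(c("pre", "zzz"))),
               "zzz")
})

test_that("Bonferroni adjustment is plain multiplication capped at 1", {
  set.seed(67)
  d <- null_metrics_table(n_subjects = 10)
  ct <- art_c_contrasts(d, "value", c("condition", "template"), "template")
  m <- nrow(ct)  # 6 pairwise template contrasts
  expect_equal(ct$p_adj, pmin(1, m * ct$p_raw))
})

test_that("chi-square matches closed forms and conserves totals", {
  even <- matrix(c(5, 5, 5, 5), 2)
  r <- chi_square_table(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  diag2 <- matrix(c(10, 0, 0, 10), 2)
  r2 <- chi_square_table(diag2)
  expect_equal(r2$statistic, 20)
  expect_equal(r2$df, 1)
  set.seed(68)
  tab <- matrix(rpois(6, 8) + 1, 2)
  r3 <- chi_square_table(tab)
  expect_equal(sum(r3$expected), sum(tab))
  expect_error(chi_square_table(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(chi_square_table(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})
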