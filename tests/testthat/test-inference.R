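test_that("RCB decomposition matches hand-computed sums of squares", {
  m <- rbind(c(1, 3), c(2, 5), c(3, 4))  # 3 blocks x 2 treatments
  fit <- rcb_anova(m)
  tab <- fit$table
  expect_equal(tab$sum_sq[tab$term == "indicator"], 6)
  expect_equal(tab$sum_sq[tab$term == "incident"], 3)
  expect_equal(tab$sum_sq[tab$term == "error"], 1)
  expect_equal(tab$F[tab$term == "indicator"], 12)
  expect_equal(tab$df, c(1L, 2L, 2L, 5L))
})

test_that("degenerate decompositions behave as limits", {
  m_same <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2)  # identical columns
  fit <- suppressWarnings(rcb_anova(m_same))
  expect_equal(fit$table$sum_sq[1], 0)
  expect_equal(fit$table$F[1], 0)
  # perfectly additive cell = block effect + treatment effect
  blocks <- c(0, 1, 4)
  treats <- c(0, 2, 5, 7)
  m_add <- outer(blocks, treats, `+`)
  expect_warning(fit2 <- rcb_anova(m_add), "zero error variance")
  expect_equal(fit2$table$sum_sq[fit2$table$term == "error"], 0,
               tolerance = 1e-12)
  expect_equal(fit2$table$p[1], 0)
  expect_error(rcb_anova(matrix(1:3, ncol = 1)), "at least 2")
})

test_that("rcb_anova agrees with the brute-force oracle and with aov", {
  set.seed(101)
  for (rep in 1:12) {
    a <- sample(2:8, 1)
    b <- sample(2:12, 1)
    m <- matrix(rnorm(a * b), nrow = b, ncol = a)
    fit <- rcb_anova(m)
    oracle <- brute_force_rcb(m)
    expect_equal(fit$table$sum_sq[1], oracle$ss_treat, tolerance = 1e-9)
    expect_equal(fit$table$sum_sq[2], oracle$ss_block, tolerance = 1e-9)
    expect_equal(fit$table$sum_sq[3], oracle$ss_error, tolerance = 1e-9)
    expect_equal(fit$table$sum_sq[4],
                 oracle$ss_treat + oracle$ss_block + oracle$ss_error,
                 tolerance = 1e-9)

    d <- data.frame(y = as.vector(m),
                    block = factor(rep(seq_len(b), a)),
                    treat = factor(rep(seq_len(a), each = b)))
    av <- summary(stats::aov(y ~ treat + block, data = d))[[1]]
    expect_equal(fit$table$F[1], av["treat", "F value"], tolerance = 1e-8)
    expect_equal(fit$table$p[1], av["treat", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("studentized range quantile matches its closed forms", {
  # k = 2: q = sqrt(2) * t quantile; agreement to 3 significant figures
  expect_equal(studentized_range_quantile(0.95, 2, 2),
               sqrt(2) * stats::qt(0.975, 2), tolerance = 1e-3)
  expect_equal(studentized_range_quantile(0.95, 2, 2), 6.085,
               tolerance = 1e-3)
  expect_equal(studentized_range_quantile(0.95, 2, 1e7),
               sqrt(2) * stats::qnorm(0.975), tolerance = 1e-3)
  # increasing in k
  qs <- vapply(2:8, function(k) studentized_range_quantile(0.95, k, 30),
               numeric(1))
  expect_true(all(diff(qs) > 0))
  expect_error(studentized_range_quantile(1.2, 3, 10), "p must be")
  expect_error(studentized_range_quantile(0.95, 1, 10), "k must be")
})

test_that("Tukey HSD threshold and flags follow the definition", {
  m <- rbind(c(1, 3), c(2, 5), c(3, 4))
  tk <- tukey_hsd(m, alpha = 0.05)
  expect_equal(tk$hsd, studentized_range_quantile(0.95, 2, 2) * sqrt(0.5 / 3),
               tolerance = 1e-9)
  expect_equal(tk$hsd, 2.484, tolerance = 1e-3)
  expect_false(tk$pairs$significant[1])  # |diff| = 2 < hsd

  # identical treatments never differ
  m2 <- cbind(c(1, 2, 3), c(1, 2, 3), c(5, 6, 9))
  tk2 <- tukey_hsd(m2)
  same <- tk2$pairs[tk2$pairs$i == "1" & tk2$pairs$j == "2", ]
  expect_equal(same$diff, 0)
  expect_false(same$significant)

  # flags are consistent with adjusted p at the same alpha
  set.seed(7)
  m3 <- matrix(rnorm(5 * 8, mean = rep(c(0, 0, 1, 3, 3), each = 8)),
               nrow = 8)
  tk3 <- tukey_hsd(m3, alpha = 0.05)
  expect_equal(tk3$pairs$significant, tk3$pairs$p_adj < 0.05)
})

test_that("for two treatments Tukey coincides with the paired t-test", {
  set.seed(202)
  for (rep in 1:20) {
    b <- sample(3:15, 1)
    m <- matrix(rnorm(2 * b, sd = 1) + rep(c(0, runif(1, 0, 2)), each = b),
                nrow = b)
    tk <- tukey_hsd(m, alpha = 0.05)
    tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
    expect_equal(tk$pairs$significant[1], tt$p.value < 0.05,
                 info = paste("rep", rep))
    # ptukey is accurate to ~4 significant digits
    expect_equal(tk$pairs$p_adj[1], tt$p.value, tolerance = 1e-3)
  }
})

test_that("line grouping emits maximal runs within the threshold", {
  g1 <- line_grouping(c(a = 1.0, b = 1.1, c = 2.0), hsd = 0.5)
  expect_equal(g1, list(c("a", "b"), "c"))
  g2 <- line_grouping(c(a = 1.0, b = 1.4, c = 1.8), hsd = 0.5)
  expect_equal(g2, list(c("a", "b"), c("b", "c")))
  g3 <- line_grouping(c(a = 1.0, b = 1.4, c = 1.8), hsd = 10)
  expect_equal(g3, list(c("a", "b", "c")))
})

test_that("grouping is sound: shared group iff difference within hsd", {
  set.seed(303)
  for (rep in 1:20) {
    k <- sample(3:11, 1)
    means <- stats::setNames(round(runif(k, 0, 2), 2), paste0("m", 1:k))
    hsd <- runif(1, 0.05, 1)
    groups <- line_grouping(means, hsd)
    expect_setequal(unique(unlist(groups)), names(means))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      together <- any(vapply(groups, function(g) {
        all(c(names(means)[i], names(means)[j]) %in% g)
      }, logical(1)))
      expect_equal(together, unname(abs(means[i] - means[j]) <= hsd),
                   info = paste(names(means)[i], names(means)[j]))
    }
  }
})

test_that("statistics are invariant to block order, equivariant to labels", {
  set.seed(404)
  m <- matrix(rnorm(44), nrow = 4, ncol = 11,
              dimnames = list(NULL, paste0("ind_", 1:11)))
  tk <- tukey_hsd(m)
  perm_blocks <- m[sample(4), ]
  tk_b <- tukey_hsd(perm_blocks)
  expect_equal(tk_b$anova$table$sum_sq, tk$anova$table$sum_sq)
  expect_equal(tk_b$hsd, tk$hsd)
  expect_equal(sort(names(tk_b$means)), sort(names(tk$means)))

  perm <- sample(11)
  tk_t <- tukey_hsd(m[, perm])
  expect_equal(tk_t$means[colnames(m)], tk$means)
  expect_equal(tk_t$anova$table$sum_sq, tk$anova$table$sum_sq,
               tolerance = 1e-12)
  expect_equal(sort(vapply(tk_t$groups, paste, collapse = ",",
                           FUN.VALUE = character(1))),
               sort(vapply(tk$groups, paste, collapse = ",",
                           FUN.VALUE = character(1))))
})

test_that("zero error variance flags every nonzero difference", {
  m <- outer(c(0, 1), c(0, 2, 2), `+`)
  # both the ANOVA fit and the HSD stage warn
  expect_warning(expect_warning(tk <- tukey_hsd(m), "zero error variance"),
                 "zero error variance")
  expect_equal(tk$pairs$significant, c(TRUE, TRUE, FALSE))
  expect_equal(tk$pairs$p_adj, c(0, 0, 1))
})
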