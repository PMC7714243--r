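test_that("ANOVA F matches brute-force sums of squares", {
  set.seed(41)
  for (rep in 1:5) {
    groups <- lapply(1:3, function(i) rnorm(sample(5:12, 1), mean = i / 2))
    names(groups) <- letters[1:3]
    expect_equal(one_way_anova(groups)$F, oracle_anova_F(groups),
                 tolerance = 1e-10)
  }
})

test_that("textbook three-group fixture reproduces F and degrees of freedom", {
  groups <- list(a = c(6, 8, 4, 5, 3, 4), b = c(8, 12, 9, 11, 6, 8),
                 c = c(13, 9, 11, 8, 7, 12))
  an <- one_way_anova(groups)
  expect_equal(an$F, oracle_anova_F(groups), tolerance = 1e-12)
  expect_equal(an$F, 9.26, tolerance = 0.005)
  expect_equal(c(an$df_between, an$df_within), c(2, 15))
})

test_that("two identical groups give F = 0, p = 1", {
  an <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
  expect_error(one_way_anova(list(a = c(1, 1), b = c(1, 1))), "degenerate")
  expect_error(one_way_anova(list(a = c(1, 2))), "at least 2 groups")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(42)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  an <- one_way_anova(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey p-values match the reference and respect symmetry", {
  set.seed(43)
  groups <- list(g1 = rnorm(8), g2 = rnorm(8, 1), g3 = rnorm(8, 3))
  tk <- tukey_hsd(groups)
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(names(groups), lengths(groups))))
  ref <- TukeyHSD(aov(value ~ group, df))$group
  expect_equal(unname(tk$pairs$p_adj),
               unname(ref[paste0(tk$pairs$group2, "-", tk$pairs$group1), "p adj"]),
               tolerance = 1e-9)
  # relabeling the groups permutes but does not change pairwise p values
  tk2 <- tukey_hsd(rev(groups))
  key <- function(t) {
    k <- apply(cbind(t$pairs$group1, t$pairs$group2), 1,
               function(r) paste(sort(r), collapse = "-"))
    setNames(t$pairs$p_adj, k)
  }
  expect_equal(key(tk)[names(key(tk))], key(tk2)[names(key(tk))],
               tolerance = 1e-12)
})

test_that("a far-shifted group produces exactly two significant pairs", {
  set.seed(44)
  groups <- list(a = rnorm(10, 0, 0.5), b = rnorm(10, 0.1, 0.5),
                 c = rnorm(10, 10, 0.5))
  tk <- tukey_hsd(groups)
  expect_identical(sum(tk$pairs$significant), 2L)
  expect_identical(sort(unname(tk$letters)), c("A", "A", "B"))
})

test_that("Tukey adjusted p decreases as the mean difference grows", {
  base <- list(a = c(-0.5, 0, 0.5, -0.2, 0.2))
  p <- vapply(c(0.5, 1, 2, 4), function(shift) {
    tukey_hsd(c(base, list(b = base$a + shift)))$pairs$p_adj
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("compact letter display covers the canonical cases", {
  mk <- function(sig) {
    list(means = c(g1 = 1, g2 = 2, g3 = 3),
         pairs = data.frame(group1 = c("g1", "g1", "g2"),
                            group2 = c("g2", "g3", "g3"),
                            significant = sig))
  }
  expect_identical(unname(letter_display(mk(c(FALSE, FALSE, FALSE)))),
                   c("A", "A", "A"))
  expect_identical(unname(letter_display(mk(c(TRUE, TRUE, TRUE)))),
                   c("A", "B", "C"))
  # chain: 1 != 3 but 1 = 2 and 2 = 3
  expect_identical(unname(letter_display(mk(c(FALSE, TRUE, FALSE)))),
                   c("A", "AB", "B"))
})

test_that("letter display is consistent with the significance pattern", {
  set.seed(45)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(6, sample(0:3, 1)))
    names(groups) <- paste0("g", seq_len(k))
    tk <- tukey_hsd(groups)
    share <- function(a, b) {
      la <- strsplit(tk$letters[a], "")[[1]]
      lb <- strsplit(tk$letters[b], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    for (i in seq_len(nrow(tk$pairs))) {
      a <- tk$pairs$group1[i]; b <- tk$pairs$group2[i]
      if (tk$pairs$significant[i]) expect_false(share(a, b))
      else expect_true(share(a, b))
    }
  }
})

test_that("condition comparison mirrors the study-table layout", {
  m <- simulate_study_metrics(n_participants = 8, seed = 46)
  cmp <- compare_conditions(m)
  # one limb x 2 metrics x 1 family present
  expect_identical(nrow(cmp), 2L)
  expect_true(all(c("sym_1.0", "asym_0.25", "asym_0.50", "p_value") %in%
                    names(cmp)))
  expect_match(cmp[["sym_1.0"]][1], "^\\d+\\.\\d \\(\\d+\\.\\d\\)")
  # missing cells are reported by name
  expect_error(compare_conditions(m[m$condition != "asym_0.50", ]),
               "asym_0.50")
})
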