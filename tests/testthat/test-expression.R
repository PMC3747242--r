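test_that("equal means give fold change 1 and fail the screen", {
  expr <- tibble::tibble(gene_id = "g1", M_1 = 10, M_2 = 10, F_1 = 10, F_2 = 10)
  rec <- differential_expression(expr)
  expect_equal(rec$fold_change, 1)
  expect_equal(rec$p_value, 1)   # zero variance, equal means
  expect_false(rec$passes)
})

test_that("t statistic and p match the textbook pooled-variance computation", {
  # log2 values M = (5.0, 5.1), F = (6.2, 6.3)
  expr <- tibble::tibble(gene_id = "g1",
                         M_1 = 2^5.0, M_2 = 2^5.1, F_1 = 2^6.2, F_2 = 2^6.3)
  rec <- differential_expression(expr)
  expect_equal(rec$direction, "F")
  expect_equal(rec$fold_change,
               (2^6.2 + 2^6.3) / (2^5.0 + 2^5.1), tolerance = 1e-12)
  expect_gt(rec$fold_change, 2.2)
  tt <- t.test(c(5.0, 5.1), c(6.2, 6.3), var.equal = TRUE)
  expect_equal(rec$t_statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(rec$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("screen requires both FC > 1.5 and p < 0.1", {
  set.seed(91)
  # strong planted effect: passes both
  hit <- tibble::tibble(gene_id = "hit",
                        M_1 = 2^8.0, M_2 = 2^8.1, M_3 = 2^7.9,
                        F_1 = 2^7.0, F_2 = 2^7.1, F_3 = 2^6.9)
  rec <- differential_expression(hit)
  expect_true(rec$fold_change > 1.5 && rec$p_value < 0.1)
  expect_true(rec$passes)
  expect_equal(rec$direction, "M")
  # large fold change but a single noisy replicate pattern -> high p fails
  noisy <- tibble::tibble(gene_id = "noisy",
                          M_1 = 2^4, M_2 = 2^12, F_1 = 2^7.9, F_2 = 2^8.1)
  expect_false(differential_expression(noisy)$passes)
})

test_that("t-test matches stats::t.test on random matrices", {
  set.seed(101)
  for (i in 1:100) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    xm <- matrix(2^rnorm(n1, 8, 1), nrow = 1)
    xf <- matrix(2^rnorm(n2, 8, 1), nrow = 1)
    expr <- tibble::tibble(gene_id = "g")
    for (j in seq_len(n1)) expr[[paste0("M_", j)]] <- xm[j]
    for (j in seq_len(n2)) expr[[paste0("F_", j)]] <- xf[j]
    rec <- differential_expression(expr)
    tt <- t.test(log2(xm[1, ]), log2(xf[1, ]), var.equal = TRUE)
    expect_equal(rec$t_statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(rec$p_value, tt$p.value, tolerance = 1e-10)
    rw <- differential_expression(expr, var_equal = FALSE)
    tw <- t.test(log2(xm[1, ]), log2(xf[1, ]))
    expect_equal(rw$p_value, tw$p.value, tolerance = 1e-10)
  }
})

test_that("fold change is label-symmetric and direction flips", {
  expr <- tibble::tibble(gene_id = c("g1", "g2"),
                         M_1 = c(20, 5), M_2 = c(22, 6),
                         F_1 = c(10, 15), F_2 = c(11, 18))
  fwd <- differential_expression(expr)
  swapped <- expr
  names(swapped) <- c("gene_id", "F_1", "F_2", "M_1", "M_2")
  rev <- differential_expression(swapped)
  expect_equal(rev$fold_change, fwd$fold_change)
  expect_equal(rev$direction, c("F", "M")[match(fwd$direction, c("M", "F"))])
  expect_equal(rev$t_statistic, -fwd$t_statistic)
})

test_that("duplicate gene rows collapse to the brightest probe", {
  expr <- tibble::tibble(gene_id = c("g1", "g1"),
                         M_1 = c(100, 2), M_2 = c(110, 3),
                         F_1 = c(50, 40), F_2 = c(55, 44))
  rec <- differential_expression(expr)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mean_m, 105)   # brightest probe kept
})

test_that("three-way integration demands consistent directions", {
  calls <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    call = c("male_dominant", "male_dominant", "female_dominant", "male_dominant"),
    n_supporting_peaks = c(1L, 1L, 2L, 1L),
    supporting_peaks = list("p1", "p2", c("p3", "p4"), "p5"),
    best_peak_score = c(7, 7, -8, 7),
    pol2_score = c(6.5, 6.5, -7, 6.5)
  )
  class(calls) <- c("dimorphism_calls", class(calls))
  recs <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    mean_m = c(20, 10, 5), mean_f = c(10, 20, 15),
    fold_change = c(2, 2, 3),
    direction = c("M", "F", "F"),
    t_statistic = c(5, -5, -6), p_value = c(0.01, 0.01, 0.01),
    passes = c(TRUE, TRUE, TRUE)
  )
  out <- integrate_three_way(calls, recs)
  expect_equal(out$final, c("male",   # concordant
                            "none",   # RNA direction conflict
                            "female", # concordant
                            "none"))  # absent from expression
  expect_false(out$rna_pass[4])
  expect_true(all(out$rxr_pass & out$pol2_pass))
})

test_that("integrated call counts shrink as cutoffs tighten", {
  set.seed(111)
  n <- 60
  expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:n))
  mu <- rnorm(n, 8, 1); eff <- sample(c(0, 1.2), n, TRUE)
  for (j in 1:3) expr[[paste0("M_", j)]] <- 2^(mu + eff / 2 + rnorm(n, 0, 0.3))
  for (j in 1:3) expr[[paste0("F_", j)]] <- 2^(mu - eff / 2 + rnorm(n, 0, 0.3))
  calls <- tibble::tibble(
    gene_id = expr$gene_id, call = "male_dominant",
    n_supporting_peaks = 1L, supporting_peaks = as.list(sprintf("p%02d", 1:n)),
    best_peak_score = 7, pol2_score = 7
  )
  class(calls) <- c("dimorphism_calls", class(calls))
  n_called <- function(fc, p) {
    sum(integrate_three_way(calls,
                            differential_expression(expr, fc_cutoff = fc,
                                                    p_cutoff = p))$final != "none")
  }
  base <- n_called(1.5, 0.1)
  expect_gte(base, n_called(2.0, 0.1))
  expect_gte(base, n_called(1.5, 0.01))
  expect_gte(n_called(1.2, 0.2), base)
})

test_that("score-expression correlation is sign-consistent", {
  scores <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                           score = seq(-8, 8, length.out = 20))
  recs <- tibble::tibble(
    gene_id = scores$gene_id,
    mean_m = 2^(8 + scores$score / 4), mean_f = 2^8,
    fold_change = pmax(2^(scores$score / 4), 2^(-scores$score / 4)),
    direction = ifelse(scores$score >= 0, "M", "F"),
    t_statistic = scores$score, p_value = 0.01, passes = TRUE
  )
  cc <- score_expression_correlation(scores, recs)
  expect_gt(cc$spearman, 0.9)
  # label swap negates the correlation
  recs_sw <- recs
  recs_sw$direction <- ifelse(recs$direction == "M", "F", "M")
  cc_sw <- score_expression_correlation(scores, recs_sw)
  expect_equal(cc_sw$pearson, -cc$pearson, tolerance = 1e-12)
  expect_warning(score_expression_correlation(scores[1:2, ], recs[1:2, ]),
                 "fewer than 3")
})
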