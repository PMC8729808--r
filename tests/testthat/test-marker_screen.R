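test_that("island level is the mean over non-missing probes", {
  m <- matrix(c(0.3, 0.3, 0.3,
                0.1, 0.2, 0.3), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("A", "B")))
  bm <- beta_matrix(m)
  lv <- island_beta(bm, c("p1", "p2", "p3"))
  expect_equal(unname(lv), c(0.3, 0.2))

  # missing probes excluded from the mean; all-missing sample warns
  m2 <- m; m2[1, 1] <- NA; m2[, 2] <- NA
  expect_warning(lv2 <- island_beta(beta_matrix(m2), c("p1", "p2", "p3")),
                 "all probes missing.*B")
  expect_equal(unname(lv2), c(0.3, NA_real_))

  # the canonical 12-probe anchor island is a valid probe set
  probes <- dualmeth:::SDC2_PROBES
  expect_length(probes, 12)
  m3 <- matrix(0.4, 12, 1, dimnames = list(probes, "A"))
  expect_equal(unname(island_beta(beta_matrix(m3), probes)), 0.4)

  expect_error(island_beta(bm, character(0)), "non-empty")
  expect_error(island_beta(bm, "nope"), "not in matrix")
})

test_that("threshold calls and hypomethylated selection partition exactly", {
  # boundary: a level equal to the threshold is negative / selected
  expect_equal(as.character(beta_call(c(0.2, 0.21, 0))),
               c("negative", "positive", "negative"))
  lv <- c(A = 0.1, B = 0.3, C = 0.2)
  expect_equal(select_hypomethylated(lv), c("A", "C"))
  expect_equal(select_hypomethylated(c(A = 0.5, B = 0.5)), character(0))

  # partition property at random levels and thresholds
  withr::with_seed(42, {
    for (i in 1:20) {
      lv <- stats::setNames(runif(30), sprintf("S%02d", 1:30))
      thr <- runif(1, 0.05, 0.95)
      hypo <- select_hypomethylated(lv, thr)
      pos <- names(lv)[beta_call(lv, thr) == "positive"]
      expect_length(intersect(hypo, pos), 0)
      expect_setequal(c(hypo, pos), names(lv))
      # monotone in level
      expect_true(all(diff(as.integer(beta_call(sort(lv), thr))) >= 0))
    }
  })
})

test_that("complement screen equals the brute-force double loop", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n_gene <- 5; n_probe <- 3; n_samp <- 10
      probes <- sprintf("g%d_p%d", rep(1:n_gene, each = n_probe), 1:n_probe)
      m <- matrix(runif(n_gene * n_probe * n_samp),
                  nrow = n_gene * n_probe,
                  dimnames = list(probes, sprintf("S%02d", 1:n_samp)))
      ann <- probe_annotation(probes, rep(sprintf("G%d", 1:n_gene),
                                          each = n_probe),
                              rep(sprintf("I%d", 1:n_gene), each = n_probe))
      hypo <- sprintf("S%02d", 1:6)
      scr <- complement_screen(beta_matrix(m), ann, hypo, threshold = 0.5)
      # oracle: explicit loop over genes and samples
      for (g in 1:n_gene) {
        means <- colMeans(m[((g - 1) * n_probe + 1):(g * n_probe), hypo])
        expected <- 100 * sum(means > 0.5) / length(hypo)
        expect_equal(scr$complement_rate[scr$gene == sprintf("G%d", g)],
                     expected)
      }
      # ranking is by rate desc, gene asc on ties
      expect_true(all(diff(scr$complement_rate) <= 0))
    }
  })

  # a gene identical to the anchor has complement rate zero by construction
  probes <- c("a1", "a2", "b1", "b2")
  m <- matrix(c(0.1, 0.1, 0.1, 0.1, 0.15, 0.15, 0.15, 0.15), nrow = 4,
              dimnames = list(probes, c("S1", "S2")))
  ann <- probe_annotation(probes, c("A", "A", "B", "B"), c("iA", "iA", "iB", "iB"))
  scr <- complement_screen(beta_matrix(m), ann, c("S1", "S2"))
  expect_equal(scr$complement_rate, c(0, 0))

  # planted complement at beta 0.6 in every hypo sample scores 100
  m[3:4, ] <- 0.6
  scr2 <- complement_screen(beta_matrix(m), ann, c("S1", "S2"))
  expect_equal(scr2$complement_rate[scr2$gene == "B"], 100)
  expect_equal(scr2$gene[1], "B")
  expect_error(complement_screen(beta_matrix(m), ann, character(0)),
               "non-empty")
})

test_that("joint OR call handles missing partners asymmetrically", {
  jp <- function(a, b) as.character(joint_positive(a, b))
  expect_equal(jp("negative", "positive"), "positive")
  expect_equal(jp("negative", "negative"), "negative")
  expect_equal(jp("positive", "positive"), "positive")
  expect_equal(jp(NA, "positive"), "positive")   # positivity established
  expect_true(is.na(jp(NA, "negative")))          # undecided
  expect_true(is.na(jp(NA, NA)))
  # vectorised
  expect_equal(jp(c("positive", "negative"), c("negative", "negative")),
               c("positive", "negative"))
})

test_that("subsite rate table reproduces counts, totals and rates", {
  counts <- utils::read.csv(extdata("tissue_screen_subsite_counts.csv"))
  fx <- expand_count_table(counts, group = "CRC")
  tab <- subsite_rate_table(fx$calls, fx$records, decimals = 1)
  tot <- tab[tab$location == "Total", ]
  expect_equal(tot$n_total, 50)
  expect_equal(tot$rate, 88.0)
  expect_equal(tab$rate[tab$location == "sigmoid_colon"], 93.3)
  # rows sum to the Total row and rates recompute from counts
  body <- tab[tab$location != "Total", ]
  expect_equal(sum(body$n_positive), tot$n_positive)
  expect_equal(sum(body$n_negative), tot$n_negative)
  expect_equal(tab$rate,
               round(100 * tab$n_positive / tab$n_total, 1),
               tolerance = 0.051)

  # degenerate location: 0 positive of 5
  fx0 <- expand_count_table(
    data.frame(location = "rectum", n_positive = 0, n_negative = 5))
  expect_equal(subsite_rate_table(fx0$calls, fx0$records)$rate, c(0, 0))
})
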