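test_that("internal-standard normalisation computes per-injection ratios", {
  vals <- tibble::tibble(
    A = c(10, 20, 6, 8), B = c(1, 4, 9, 10), IS_1 = c(5, 10, 3, 4)
  )
  tab <- make_raw_table(vals, sprintf("S%d", c(1, 1, 2, 2)),
                        rep(c("NW", "OW/Ob"), each = 2), c(1, 2, 1, 2))
  out <- normalize_to_internal_standard(tab, c(A = "IS_1", B = "IS_1"))
  expect_equal(out$A, vals$A / vals$IS_1)
  expect_equal(out$B, vals$B / vals$IS_1)
  expect_false("IS_1" %in% names(out))

  # feature identical to its standard -> all ones
  tab2 <- make_raw_table(tibble::tibble(A = c(3, 7), IS_1 = c(3, 7)),
                         c("S1", "S2"), c("NW", "OW/Ob"), c(1, 1))
  expect_equal(normalize_to_internal_standard(tab2, c(A = "IS_1"))$A, c(1, 1))

  # hand-computed random 4 x 3 case
  withr::with_seed(5, {
    M <- matrix(runif(12, 1, 10), 4, 3, dimnames = list(NULL, c("F1", "F2", "F3")))
  })
  is_col <- c(2, 3, 5, 7)
  tab3 <- make_raw_table(
    dplyr::bind_cols(tibble::as_tibble(M), tibble::tibble(IS_1 = is_col)),
    sprintf("S%d", 1:4), rep(c("NW", "OW/Ob"), 2), rep(1, 4)
  )
  out3 <- normalize_to_internal_standard(
    tab3, c(F1 = "IS_1", F2 = "IS_1", F3 = "IS_1")
  )
  expect_equal(as.matrix(out3[c("F1", "F2", "F3")]), M / is_col,
               ignore_attr = TRUE)
})

test_that("a missing or zero standard peak names the injection", {
  tab <- make_raw_table(tibble::tibble(A = c(1, 2), IS_1 = c(5, 0)),
                        c("S1", "S2"), c("NW", "OW/Ob"), c(1, 1))
  expect_error(normalize_to_internal_standard(tab, c(A = "IS_1")),
               "IS_1.*injection 2", class = "voclearn_error_normalization")
  tab$IS_1 <- c(NA, 5)
  expect_error(normalize_to_internal_standard(tab, c(A = "IS_1")),
               class = "voclearn_error_normalization")
})

test_that("replicate collapse takes robust medians and keeps missingness rules", {
  tab <- make_raw_table(
    tibble::tibble(A = c(1, 2, 30), B = c(4, NA, 6), C = c(NA, NA, NA)),
    rep("S1", 3), rep("NW", 3), 1:3
  )
  tab <- dplyr::bind_rows(tab, make_raw_table(
    tibble::tibble(A = 9, B = 9, C = 9), "S2", "OW/Ob", 1
  ))
  out <- collapse_replicates(tab)
  expect_equal(out$A, c(2, 9))    # median robust to the 30
  expect_equal(out$B, c(5, 9))    # median of non-missing {4, 6}
  expect_equal(out$C, c(NA, 9))   # missing iff all replicates missing
  # idempotent once one row per subject (replicate column re-attached)
  again <- collapse_replicates(dplyr::mutate(out, replicate = 1))
  expect_equal(again, out)
})

test_that("log-autoscale centres, scales and honours the missing policy", {
  tab <- make_raw_table(
    tibble::tibble(A = exp(1:3), B = c(2, NA, 8), C = c(5, 5, 5)),
    sprintf("S%d", 1:3), c("NW", "NW", "OW/Ob")
  )
  expect_warning(out <- log_autoscale(tab), "constant")
  expect_equal(out$A, c(-1, 0, 1))
  expect_false("C" %in% names(out))
  # half-min imputation: NA -> min/2 = 1, log = 0
  expect_equal(attr(out, "log_data")$B, c(log(2), 0, log(8)))
  # autoscaling postcondition
  X <- as.matrix(out[c("A", "B")])
  expect_true(all(abs(colMeans(X)) < 1e-10))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-10))

  out2 <- suppressWarnings(log_autoscale(tab, missing_policy = "drop_feature"))
  expect_setequal(setdiff(names(out2), c("subject_id", "group")), "A")

  # all-missing feature: warning, never an error
  tab$B <- NA_real_
  expect_warning(log_autoscale(tab[c("subject_id", "group", "B")]),
                 "all subjects")
})

test_that("autoscaled logs are invariant to positive rescaling of a feature", {
  tab <- make_raw_table(
    tibble::as_tibble(matrix(exp(rnorm(24)), 6, 4,
                             dimnames = list(NULL, paste0("F", 1:4)))),
    sprintf("S%d", 1:6), rep(c("NW", "OW/Ob"), 3)
  )
  out1 <- log_autoscale(tab)
  tab$F2 <- tab$F2 * 1000
  out2 <- log_autoscale(tab)
  expect_equal(out1$F2, out2$F2, tolerance = 1e-10)
})

test_that("preprocessing commutes with subject order", {
  ch <- generate_cohort(cohort_spec(n_group1 = 6, n_group2 = 6, n_features = 8,
                                    n_informative = 0, seed = 9,
                                    occurrence_probs = 0.8))
  pipeline <- function(tab) {
    log_autoscale(collapse_replicates(
      normalize_to_internal_standard(tab, ch$is_mapping)
    ))
  }
  out <- pipeline(ch$table)
  perm <- withr::with_seed(1, sample(nrow(ch$table)))
  out_perm <- pipeline(ch$table[perm, ])
  reord <- match(out$subject_id, out_perm$subject_id)
  expect_equal(as.data.frame(out_perm[reord, names(out)]),
               as.data.frame(out), ignore_attr = TRUE)
})

test_that("Kovats indices interpolate between bracketing alkanes", {
  alk <- setNames(c(2, 5, 10, 20), 8:11)
  expect_equal(kovats_index(10, alk), 1000)
  expect_equal(kovats_index(10, alk, "logarithmic"), 1000)
  expect_equal(kovats_index(15, alk), 1050)
  expect_equal(kovats_index(7.5, alk), 950)
  # isothermal form: rt at the log-midpoint of C10-C11
  expect_equal(kovats_index(10 * sqrt(2), alk, "logarithmic"), 1050)
  expect_error(kovats_index(1, alk), class = "voclearn_error_range")
  expect_error(kovats_index(25, alk), class = "voclearn_error_range")
  expect_error(kovats_index(10, setNames(c(2, 5, 4, 20), 8:11)),
               class = "voclearn_error_input")
  expect_error(kovats_index(10, setNames(c(2, 5, 10), c(8, 9, 11))),
               class = "voclearn_error_input")
})

test_that("HOMA-IR follows the insulin x glucose / 22.5 formula", {
  expect_equal(homa_ir(22.5, 1), 1)
  expect_equal(homa_ir(10, 5), 100 / 45)
  expect_error(homa_ir(0, 5), class = "voclearn_error_parameter")
  expect_error(homa_ir(5, -1), class = "voclearn_error_parameter")
})

test_that("summary-statistics Welch test matches t.test on raw data", {
  withr::with_seed(4, {
    x <- rnorm(12, 1, 2)
    y <- rnorm(9, 0, 1)
  })
  ref <- t.test(x, y)
  out <- welch_t_from_summary(mean(x), sd(x), 12, mean(y), sd(y), 9)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(out$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(out$p, ref$p.value, tolerance = 1e-12)
  # equal means -> t = 0, p = 1
  eq <- welch_t_from_summary(5, 1, 10, 5, 2, 8)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_error(welch_t_from_summary(1, 1, 1, 0, 1, 5),
               class = "voclearn_error_parameter")
})

test_that("VOC identification tables parse into complete records", {
  acid <- parse_voc_table(voc_fixture("table2_acid_vocs"), condition = "acid")
  hept <- acid[acid$metabolite == "4-Heptanone", ]
  expect_equal(hept$mz_values[[1]], c(43L, 71L))
  expect_equal(hept$occurrence_nw, 100)
  expect_equal(hept$occurrence_ow, 100)
  expect_equal(hept$id_method, "RI/MS")
  expect_equal(hept$ri_cal, 1134)
  expect_equal(hept$ri_lit, 1131)
  # missing RI cells come back absent, not zero
  expect_true(any(is.na(acid$ri_cal)))
  expect_false(any(acid$ri_cal == 0, na.rm = TRUE))

  bad <- withr::local_tempfile(fileext = ".tsv")
  tbl <- readr::read_tsv(voc_fixture("table2_acid_vocs"),
                         show_col_types = FALSE)
  tbl$occurrence_nw[7] <- 150
  readr::write_tsv(tbl, bad)
  expect_error(suppressWarnings(parse_voc_table(bad)), "line.*7",
               class = "voclearn_error_parse")
})
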