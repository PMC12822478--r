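
test_that("KSEA z matches the direct formula on a constructed background", {
  set.seed(77)
  rest <- constructed_background()
  vals <- c(rep(1, 4), rest)
  names(vals) <- c(paste0("SUB_S", 1:4), paste0("BG_S", 1:96))
  expect_equal(mean(vals), 0, tolerance = 1e-12)
  expect_equal(sd(vals), 1, tolerance = 1e-12)
  map <- list(KIN1 = paste0("SUB_S", 1:4))
  res <- ksea_scores(vals, map)
  expect_equal(res$activities$z, 2.0, tolerance = 1e-9)  # (1-0)*sqrt(4)/1
  expect_equal(res$activities$p, 2 * pnorm(-2), tolerance = 1e-9)
  expect_equal(res$activities$m, 4)
})

test_that("KSEA handles degenerate and excluded kinases", {
  set.seed(78)
  vals <- stats::setNames(rnorm(50), paste0("G", 1:50, "_S1"))
  map <- list(
    NULLKIN = names(vals)[1:10],
    TINY = names(vals)[1:2],                 # below min_substrates
    ABSENT = c("NOPE_S1", "NOPE_S2", "NOPE_S3")
  )
  # kinase whose substrate mean equals the background mean -> z ~ 0
  vals[1:10] <- vals[1:10] - mean(vals[1:10]) + mean(vals)
  res <- suppressMessages(ksea_scores(vals, map))
  expect_equal(res$activities$kinase, "NULLKIN")
  expect_lt(abs(res$activities$z[1]), 0.3)
  expect_equal(res$n_excluded, 2L)
  expect_error(ksea_scores(stats::setNames(rep(1, 30), paste0("G", 1:30, "_S1")),
                           map), "standard deviation is zero")
  expect_error(ksea_scores(vals[1:5], map), ">= 20")
})

test_that("KSEA z is invariant to adding a constant to all contrasts", {
  set.seed(79)
  vals <- stats::setNames(rnorm(60), paste0("G", 1:60, "_S1"))
  map <- list(K = names(vals)[1:6])
  z1 <- ksea_scores(vals, map)$activities$z
  z2 <- ksea_scores(vals + 5, map)$activities$z
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("planted kinases dominate the activity ranking on a synthetic cohort", {
  # no planted tissue/subtype effects and complete quantification: the KSEA
  # background is then pure noise, the condition under which the z formula's
  # calibration is interpretable (MNAR missingness adds an abundance-dependent
  # per-kinase contrast bias, exercised elsewhere)
  b <- generate_cohort(small_cohort_config(701, n_patients = 34, n_genes = 800,
                                           n_metabolism = 0,
                                           n_rna_function = 0, n_cis_genes = 80,
                                           n_lm_up = 0, n_t_up = 0,
                                           subtype_effect = 0,
                                           mcar_rate = 0, mnar_mid = -99))
  phos <- normalized_layers(b)$phosphosite
  cl <- b$clinical
  contrast <- site_contrast(phos, tissue_samples(cl, "LM"), tissue_samples(cl, "T"),
                            paired = TRUE, patients = patient_map(cl))
  res <- suppressMessages(ksea_scores(contrast, b$kinase_map))
  top5 <- res$activities$kinase[1:5]
  expect_setequal(top5, b$truth$active_kinases)
  expect_true(all(res$activities$q[1:5] < 0.05))
})

test_that("substrate evidence table conserves substrate counts", {
  set.seed(80)
  vals <- stats::setNames(c(rnorm(40), rnorm(10) + 2), paste0("G", 1:50, "_S1"))
  map <- list(ACT = names(vals)[41:50], NULLK = names(vals)[1:10])
  res <- ksea_scores(vals, map)
  diff_rec <- data.frame(feature = names(vals), log2fc = unname(vals),
                         p = runif(50), q = runif(50))
  evid <- substrate_annotation(res$activities, map, diff_rec, alpha = 0.05)
  reported <- unique(evid$kinase)
  expect_equal(nrow(evid), sum(lengths(map[reported])))
  # substrate missing from diff records is flagged
  evid2 <- substrate_annotation(res$activities, map,
                                diff_rec[-50, ], alpha = 0.05)
  expect_false(all(evid2$in_diff_records))
})
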