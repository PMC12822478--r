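# Small constructed cohort for cascade mechanics: 24 patients, 72 samples,
# one planted C1-LM-specific marker plus controlled failure cases.
cascade_fixture <- function(seed = 1, n_pat = 24) {
  set.seed(seed)
  patients <- sprintf("P%02d", seq_len(n_pat))
  subtype <- rep(c("C1", "C2"), length.out = n_pat)
  cl <- data.frame(
    patient_id = rep(patients, each = 3),
    sample_id = paste0(rep(patients, each = 3), "_", rep(c("N", "T", "LM"), n_pat)),
    tissue = rep(c("N", "T", "LM"), n_pat),
    os_time = 0, os_event = 0
  )
  # C1 patients die fast, C2 slowly (so a C1-tracking marker is prognostic)
  death <- rexp(n_pat, rate = ifelse(subtype == "C1", 0.01, 0.001))
  cl$os_time <- ceiling(rep(death, each = 3) * 30)
  cl$os_event <- 1
  v <- matrix(rnorm(8 * nrow(cl), sd = 0.4), 8,
              dimnames = list(sprintf("F%02d", 1:8), cl$sample_id))
  c1_lm <- cl$sample_id[cl$tissue == "LM" &
                          rep(subtype, each = 3)[match(cl$sample_id, cl$sample_id)] == "C1"]
  c1_lm <- cl$sample_id[cl$tissue == "LM" & cl$patient_id %in% patients[subtype == "C1"]]
  v["F01", c1_lm] <- v["F01", c1_lm] + 2          # true marker
  v["F02", ] <- v["F02", ]                         # null
  v["F03", c1_lm] <- v["F03", c1_lm] + 2           # marker but too missing
  v["F03", sample(ncol(v), ceiling(0.12 * ncol(v)))] <- NA
  # F04 high in C1-LM and C1-N (fails the C1-N comparison)
  c1_n <- cl$sample_id[cl$tissue == "N" & cl$patient_id %in% patients[subtype == "C1"]]
  v["F04", c(c1_lm, c1_n)] <- v["F04", c(c1_lm, c1_n)] + 2
  m <- toy_matrix(v, features = rownames(v), samples = colnames(v))
  cl_sub <- attach_subtypes(cl, stats::setNames(subtype, patients))
  list(matrix = m, clinical = cl_sub, subtype = subtype)
}

test_that("protein cascade passes a planted marker and names failing stages", {
  fx <- cascade_fixture()
  res <- suppressMessages(protein_biomarker_scan(fx$matrix, fx$clinical))
  rec <- res$records
  expect_true("F01" %in% res$passing)
  expect_equal(rec$failed_stage[rec$feature == "F03"], "missingness")
  expect_gt(rec$missing_frac[rec$feature == "F03"], 0.10)
  expect_equal(rec$failed_stage[rec$feature == "F04"], "differential:C1-N")
  # null feature fails the differential stage somewhere
  expect_true(startsWith(rec$failed_stage[rec$feature == "F02"], "differential"))
  # audit-trail invariant: final status is the conjunction of stage passes
  expect_equal(rec$final_pass, is.na(rec$failed_stage))
})

test_that("protein cascade requires subtype labels", {
  fx <- cascade_fixture()
  cl <- fx$clinical; cl$subtype <- NULL
  expect_error(protein_biomarker_scan(fx$matrix, cl), "subtype")
})

test_that("cascade is monotone: loosening thresholds never drops a pass", {
  fx <- cascade_fixture(seed = 3)
  strict <- suppressMessages(protein_biomarker_scan(fx$matrix, fx$clinical,
                                                    policy = cascade_policy()))
  loose <- suppressMessages(protein_biomarker_scan(
    fx$matrix, fx$clinical,
    policy = cascade_policy(max_missing = 0.2, protein_fc = 1.1,
                            max_p = 0.1, max_logrank_p = 0.1)
  ))
  expect_true(all(strict$passing %in% loose$passing))
})

test_that("phospho cascade gates on fold change, functional score and survival", {
  fx <- cascade_fixture(seed = 5)
  v <- fx$matrix$values
  rownames(v) <- paste0("G0", 1:8, "_S", 11:18)
  phos <- omics_matrix(v, "phosphosite", is_normalized = TRUE)
  ann <- data.frame(
    site_id = rownames(v),
    functional_score = c(0.8, 0.8, 0.8, 0.4, rep(0.8, 4)),
    localization_class = "I"
  )
  res <- suppressMessages(phospho_biomarker_scan(phos, ann, fx$clinical))
  rec <- res$records
  expect_true("G01_S11" %in% res$passing)       # planted C1-vs-C2 site
  # G04 has a big C1-LM shift (differential passes) but score 0.4
  expect_equal(rec$failed_stage[rec$feature == "G04_S14"], "functional_score")
  expect_equal(rec$failed_stage[rec$feature == "G03_S13"], "missingness")
  # null sites fail the differential stage (FC or p)
  expect_true(startsWith(rec$failed_stage[rec$feature == "G02_S12"], "differential"))
})

test_that("dependency intersection deduplicates and ranks by significance", {
  fx <- cascade_fixture(seed = 7)
  lists <- list(crc = c("F01", "F02", "ZZZ"), liver = c("F01", "F05"))
  res <- suppressMessages(dependency_intersect(c("F01", "F02", "F05"), lists,
                                               fx$matrix, fx$clinical))
  expect_equal(sort(res$gene), c("F01", "F02", "F05"))
  expect_equal(res$sources[res$gene == "F01"], "crc;liver")
  expect_equal(res$gene[1], "F01")  # planted LM-vs-T effect ranks first
  expect_true(all(diff(res$p) >= 0))
  empty <- dependency_intersect("F08", list(crc = "F01"), fx$matrix, fx$clinical)
  expect_equal(nrow(empty), 0)
  expect_error(dependency_intersect("F01", list(), fx$matrix, fx$clinical),
               "non-empty")
})

test_that("null cohorts produce final-pass counts within the independence bound", {
  b <- generate_cohort(null_cohort_config(901, n_patients = 24))
  prot <- normalized_layers(b)$protein
  cl <- attach_subtypes(b$clinical, b$truth$subtype)
  res <- suppressMessages(protein_biomarker_scan(prot, cl))
  n_candidates <- sum(res$records$missing_frac < 0.10)
  # differential (all five at p < .05 with consistent direction) x survival
  bound <- n_candidates * 0.05 * 0.05
  expect_lte(length(res$passing), max(3, 3 * bound))
})
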