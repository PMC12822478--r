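toy_as_table <- function(fdr, delta, psi = NULL, n_samples = 6) {
  n <- length(fdr)
  ev <- data.frame(
    event_id = sprintf("E%02d", seq_len(n)), gene = sprintf("G%02d", seq_len(n)),
    event_type = "SE", inc_level_difference = delta, fdr = fdr
  )
  if (is.null(psi)) {
    psi <- matrix(runif(n * n_samples), n)
  }
  dimnames(psi) <- list(ev$event_id, sprintf("S%02d", seq_len(ncol(psi))))
  structure(list(events = ev, psi = psi), class = "as_event_table")
}

test_that("AS event filter applies both thresholds strictly on absolute delta", {
  set.seed(1)
  tbl <- toy_as_table(fdr = c(0.01, 0.01, 0.001, 0.05, 0.049),
                      delta = c(0.15, 0.05, -0.2, 0.5, 0.1))
  kept <- filter_as_events(tbl)
  expect_equal(kept$events$event_id, c("E01", "E03"))
  # E02 fails |delta| > 0.1; E04 fails fdr < 0.05; E05 fails |delta| strictly
  expect_equal(nrow(kept$psi), 2)
  # monotone in both thresholds
  k_loose <- filter_as_events(tbl, fdr_max = 0.1, min_abs_delta = 0.04)
  expect_true(all(kept$events$event_id %in% k_loose$events$event_id))
})

test_that("AS survival scan skips degenerate events and finds planted ones", {
  set.seed(2)
  n <- 40
  cl <- data.frame(patient_id = paste0("P", 1:n), sample_id = sprintf("S%02d", 1:n),
                   tissue = "LM", os_time = 0, os_event = 1)
  grp <- rep(c(0, 1), each = n / 2)
  cl$os_time <- ceiling(rexp(n, rate = 0.001 * 3^grp) * 1)
  psi <- rbind(
    plogis(grp * 2 + rnorm(n, sd = 0.3)),  # tracks the hazard group
    rep(0.5, n),                            # constant -> skipped
    runif(n)                                # null
  )
  tbl <- toy_as_table(fdr = rep(0.01, 3), delta = rep(0.3, 3), psi = psi,
                      n_samples = n)
  res <- suppressMessages(as_survival_scan(tbl, cl))
  expect_equal(res$n_skipped, 1L)
  expect_false("E02" %in% res$records$event_id)
  expect_lt(res$records$logrank_p[res$records$event_id == "E01"], 0.05)
  expect_equal(res$records$prognosis[res$records$event_id == "E01"], "poor")
  # identical strata -> p = 1
  psi_id <- rbind(rep(c(0.2, 0.8), n / 2))
  cl2 <- cl; cl2$os_time <- rep(c(10, 20), n / 2); cl2$os_event <- 1
  tbl2 <- toy_as_table(0.01, 0.3, psi = rbind(c(rep(0.2, n / 2), rep(0.8, n / 2))),
                       n_samples = n)
  cl2$os_time <- rep(1:(n / 2), 2); cl2$os_event <- 1
  res2 <- suppressMessages(as_survival_scan(tbl2, cl2))
  expect_gt(res2$records$logrank_p[1], 0.99)
})

test_that("factor-event network edges match a brute-force grid", {
  set.seed(3)
  n <- 30
  prot_v <- matrix(rnorm(3 * n), 3, dimnames = list(c("FA", "FB", "FC"),
                                                    sprintf("S%02d", 1:n)))
  psi <- matrix(runif(3 * n), 3)
  psi[1, ] <- plogis(scale(prot_v["FA", ])[, 1] * 3 + rnorm(n, sd = 0.1))
  tbl <- toy_as_table(rep(0.01, 3), rep(0.3, 3), psi = psi, n_samples = n)
  prot <- omics_matrix(prot_v, "protein", is_normalized = TRUE)
  net <- factor_event_network(prot, c("FA", "FB", "FC"), tbl)
  expect_equal(nrow(net$all_pairs), 9)
  # brute-force recount of significant pairs
  brute <- expand.grid(f = c("FA", "FB", "FC"), e = 1:3)
  brute_p <- mapply(function(f, e) {
    spearman_corr(prot_v[f, ], psi[e, ])$p
  }, as.character(brute$f), brute$e)
  brute_q <- p.adjust(brute_p, "BH")
  expect_equal(nrow(net$edges), sum(brute_q < 0.05))
  expect_true(all(net$edges$q < 0.05))
  # the planted positive edge is recovered with the right sign
  top <- net$edges[1, ]
  expect_equal(top$factor, "FA"); expect_equal(top$event_id, "E01")
  expect_equal(top$sign, 1)
  # perfect rank agreement gives rho = 1
  psi2 <- psi; psi2[2, ] <- plogis(prot_v["FB", ])
  tbl2 <- toy_as_table(rep(0.01, 3), rep(0.3, 3), psi = psi2, n_samples = n)
  net2 <- factor_event_network(prot, "FB", tbl2)
  expect_equal(net2$all_pairs$rho[net2$all_pairs$event_id == "E02"], 1)
})

test_that("network is reproducible under sample reordering", {
  set.seed(4)
  n <- 20
  prot_v <- matrix(rnorm(2 * n), 2, dimnames = list(c("FA", "FB"), sprintf("S%02d", 1:n)))
  psi <- matrix(runif(2 * n), 2)
  tbl <- toy_as_table(rep(0.01, 2), rep(0.3, 2), psi = psi, n_samples = n)
  prot <- omics_matrix(prot_v, "protein", is_normalized = TRUE)
  perm <- sample(n)
  prot_p <- omics_matrix(prot_v[, perm], "protein", is_normalized = TRUE)
  a <- factor_event_network(prot, c("FA", "FB"), tbl)$all_pairs
  b <- factor_event_network(prot_p, c("FA", "FB"), tbl)$all_pairs
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
})

test_that("null factor-event pairs are retained at about the nominal rate", {
  set.seed(5)
  hits <- replicate(30, {
    n <- 30
    x <- rnorm(n); y <- runif(n)
    spearman_corr(x, y)$p < 0.05
  })
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 30))
})
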