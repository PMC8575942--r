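# Instrument selection, clumping, allele harmonisation and the
# annotation screen.

test_that("instrument selection applies threshold and replication flags", {
  ss <- make_ss(data.frame(variant_id = c("rs1", "rs2"),
                           effect_allele = "A", other_allele = "G", eaf = 0.3,
                           beta = c(qnorm(1e-9 / 2) * 0.01, qnorm(1e-7 / 2) * 0.01),
                           se = 0.01))
  sel <- select_instruments(ss, 5e-8)
  expect_equal(sel$variant_id, "rs1")

  all_sel <- select_instruments(ss, 1.0)
  expect_equal(nrow(all_sel), 2)

  ss3 <- make_ss(data.frame(variant_id = c("rs1", "rs2", "rs3"),
                            effect_allele = "A", other_allele = "G", eaf = 0.3,
                            beta = 0.1, se = 0.01))
  flags <- c(rs1 = TRUE, rs2 = FALSE, rs3 = TRUE)
  expect_equal(select_instruments(ss3, 5e-8, flags)$variant_id, c("rs1", "rs3"))
})

test_that("greedy clumping keeps the lowest-p index and discards linked variants", {
  ld <- ld_reference(data.frame(id_a = "rs1", id_b = "rs2", r2 = 0.5))
  cand <- data.frame(variant_id = c("rs2", "rs1"), pvalue = c(1e-9, 1e-10))
  expect_equal(clump(cand, ld, 0.001), "rs1")

  # all independent: everything kept
  cand3 <- data.frame(variant_id = c("rsA", "rsB", "rsC"), pvalue = c(1e-10, 1e-9, 1e-8))
  expect_equal(clump(cand3, ld_reference(), 0.001), c("rsA", "rsB", "rsC"))
})

test_that("clumping matches a brute-force greedy oracle on a 5-variant chain", {
  ids <- paste0("rs", 1:5)
  pairs <- data.frame(id_a = ids[1:4], id_b = ids[2:5], r2 = c(0.9, 0.0005, 0.7, 0.9))
  pairs <- rbind(pairs, data.frame(id_a = "rs1", id_b = "rs4", r2 = 0.3))
  ld <- ld_reference(pairs)
  cand <- data.frame(variant_id = ids, pvalue = c(1e-12, 1e-8, 1e-10, 1e-9, 1e-11))

  # independent oracle: explicit greedy loop over the p-sorted candidates
  oracle <- function(cand, pairs, thr) {
    look <- function(a, b) {
      hit <- (pairs$id_a == a & pairs$id_b == b) | (pairs$id_a == b & pairs$id_b == a)
      if (any(hit)) pairs$r2[hit][1] else 0
    }
    left <- cand[order(cand$pvalue, cand$variant_id), "variant_id"]
    kept <- character(0)
    while (length(left)) {
      kept <- c(kept, left[1])
      left <- left[-1][vapply(left[-1], function(v) look(left[1], v) < thr, logical(1))]
    }
    kept
  }
  expect_equal(clump(cand, ld, 0.5), oracle(cand, pairs, 0.5))
  expect_equal(clump(cand, ld, 0.001), oracle(cand, pairs, 0.001))

  # order independence (ties broken lexicographically)
  shuffled <- cand[c(4, 2, 5, 1, 3), ]
  expect_equal(clump(shuffled, ld, 0.5), clump(cand, ld, 0.5))
  tie <- data.frame(variant_id = c("rsB", "rsA"), pvalue = c(1e-9, 1e-9))
  expect_equal(clump(tie, ld_reference(data.frame(id_a = "rsA", id_b = "rsB", r2 = 0.9)),
                     0.5), "rsA")
})

test_that("merging instruments across exposures retains the minimum p", {
  a <- data.frame(variant_id = c("rs1", "rs2", "rs3"), pvalue = c(1e-10, 1e-9, 1e-8))
  b <- data.frame(variant_id = c("rs1", "rs4"), pvalue = c(1e-9, 1e-12))
  merged <- merge_exposure_instruments(list(a, b))
  expect_equal(nrow(merged), 4)
  expect_equal(merged$pvalue[merged$variant_id == "rs1"], 1e-10)
  expect_equal(merged$variant_id[1], "rs4")

  disj <- merge_exposure_instruments(list(a[1:3, ], data.frame(
    variant_id = paste0("x", 1:4), pvalue = rep(1e-9, 4))))
  expect_equal(nrow(disj), 7)
})

exposure_1snp <- function(ea, oa, beta = 0.1, eaf = 0.2) {
  make_ss(data.frame(variant_id = "rs1", effect_allele = ea, other_allele = oa,
                     eaf = eaf, beta = beta, se = 0.01, n = 1000))
}
outcome_1snp <- function(ea, oa, beta, eaf = 0.2) {
  make_ss(data.frame(variant_id = "rs1", effect_allele = ea, other_allele = oa,
                     eaf = eaf, beta = beta, se = 0.02, n = 2000))
}

test_that("outcome effects are sign-flipped when alleles are swapped", {
  hs <- harmonise(exposure_1snp("A", "G"), outcome_1snp("G", "A", -0.1, eaf = 0.8), "rs1")
  expect_equal(n_snps(hs), 1)
  expect_equal(hs$outcome_beta, 0.1)
})

test_that("ambiguous palindromes are excluded and clear ones frequency-aligned", {
  # eaf 0.5: inside the (0.42, 0.58) window, no proxy -> excluded
  hs <- harmonise(exposure_1snp("A", "T", eaf = 0.5), outcome_1snp("A", "T", 0.1, eaf = 0.5), "rs1")
  expect_equal(n_snps(hs), 0)
  expect_equal(hs$exclusion_log$reason, "palindrome-ambiguous")

  # window endpoints are exclusive: eaf exactly 0.42 is alignable
  hs_edge <- harmonise(exposure_1snp("A", "T", eaf = 0.42),
                       outcome_1snp("A", "T", 0.1, eaf = 0.42), "rs1")
  expect_equal(n_snps(hs_edge), 1)
  expect_equal(hs_edge$outcome_beta, 0.1)

  # complementary-strand report: exposure eaf 0.10, outcome states eaf 0.88
  # for the same letter -> minor-allele matching flips the sign
  hs_flip <- harmonise(exposure_1snp("A", "T", eaf = 0.10),
                       outcome_1snp("A", "T", 0.1, eaf = 0.88), "rs1")
  expect_equal(n_snps(hs_flip), 1)
  expect_equal(hs_flip$outcome_beta, -0.1)

  # missing frequency on either side -> excluded
  hs_na <- harmonise(exposure_1snp("A", "T", eaf = NA),
                     outcome_1snp("A", "T", 0.1, eaf = 0.2), "rs1")
  expect_equal(hs_na$exclusion_log$reason, "palindrome-ambiguous")
})

test_that("alignment recovers the correct sign for every allele representation", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  for (ea in bases) for (oa in setdiff(bases, ea)) {
    exp_tab <- exposure_1snp(ea, oa, beta = 0.1, eaf = 0.2)
    pal <- comp[[ea]] == oa
    reps <- list(
      same = list(ea = ea, oa = oa, beta = 0.05, eaf = 0.2),
      swapped = list(ea = oa, oa = ea, beta = -0.05, eaf = 0.8),
      strand = list(ea = comp[[ea]], oa = comp[[oa]], beta = 0.05, eaf = 0.2),
      strand_swapped = list(ea = comp[[oa]], oa = comp[[ea]], beta = -0.05, eaf = 0.8))
    for (nm in names(reps)) {
      r <- reps[[nm]]
      hs <- harmonise(exp_tab, outcome_1snp(r$ea, r$oa, r$beta, eaf = r$eaf), "rs1")
      expect_equal(n_snps(hs), 1, info = paste(ea, oa, nm))
      expect_equal(hs$outcome_beta, 0.05, info = paste(ea, oa, nm))
    }
    # incompatible letters are a mismatch for non-palindromic pairs
    if (!pal) {
      other <- setdiff(bases, c(ea, oa, comp[[ea]], comp[[oa]]))
      if (length(other)) {
        hs_bad <- harmonise(exp_tab, outcome_1snp(other[1], ea, 0.05), "rs1")
        expect_equal(hs_bad$exclusion_log$reason, "allele-mismatch")
      }
    }
  }
})

test_that("harmonisation is involutive under exposure allele relabelling", {
  tr <- quick_truth(n_snps = 50, seed = 11)
  st <- generate_study(tr)
  cand <- select_instruments(st$exposures$sbp)$variant_id
  hs1 <- harmonise(st$exposures$sbp, st$outcomes$cvd, cand, ld = st$ld)

  relabelled <- st$exposures$sbp
  d <- relabelled$data
  relabelled$data$effect_allele <- d$other_allele
  relabelled$data$other_allele <- d$effect_allele
  relabelled$data$beta <- -d$beta
  relabelled$data$eaf <- 1 - d$eaf
  hs2 <- harmonise(relabelled, st$outcomes$cvd, cand, ld = st$ld)

  expect_equal(hs2$variant_ids, hs1$variant_ids)
  # both sides flip sign together: the Wald estimand is unchanged
  expect_equal(hs2$exposure_betas[, 1], -hs1$exposure_betas[, 1])
  expect_equal(hs2$outcome_beta, -hs1$outcome_beta)
  expect_equal(mr_ivw(hs2)$estimate, mr_ivw(hs1)$estimate, tolerance = 1e-12)
  expect_equal(hs2$exclusion_log, hs1$exclusion_log)
})

test_that("missing outcome variants use proxies when available, else are logged", {
  exp_tab <- make_ss(data.frame(variant_id = c("rs1", "rs1_p", "rs2"),
                                effect_allele = "A", other_allele = "G",
                                eaf = c(0.3, 0.3, 0.4), beta = c(0.02, 0.019, 0.03),
                                se = 0.003, n = 1000))
  out_tab <- make_ss(data.frame(variant_id = c("rs1_p", "rs2"),
                                effect_allele = "A", other_allele = "G",
                                eaf = c(0.3, 0.4), beta = c(0.01, 0.02),
                                se = 0.005, n = 2000))
  ld <- ld_reference(proxies = data.frame(missing_id = "rs1", proxy_id = "rs1_p", r2 = 0.9))
  hs <- harmonise(exp_tab, out_tab, c("rs1", "rs2"), ld = ld)
  expect_setequal(hs$variant_ids, c("rs1_p", "rs2"))
  expect_equal(hs$exclusion_log$reason, "proxy-substituted")

  # below the r2 floor the proxy is not used
  ld_low <- ld_reference(proxies = data.frame(missing_id = "rs1", proxy_id = "rs1_p", r2 = 0.5))
  hs2 <- harmonise(exp_tab, out_tab, c("rs1", "rs2"), ld = ld_low)
  expect_equal(hs2$variant_ids, "rs2")
  expect_equal(hs2$exclusion_log$reason, "missing-in-outcome")
})

test_that("instrument accounting: every instrument is harmonised or terminally excluded", {
  tr <- quick_truth(n_snps = 120, seed = 9)
  st <- generate_study(tr)
  cand <- merge_exposure_instruments(lapply(st$exposures, select_instruments))
  hs <- harmonise(st$exposures, st$outcomes$cvd, cand$variant_id, ld = st$ld)
  terminal <- hs$exclusion_log[hs$exclusion_log$reason != "proxy-substituted", ]
  expect_equal(n_snps(hs) + nrow(terminal), nrow(cand))
  expect_false(any(terminal$variant_id %in% hs$variant_ids))
})

test_that("LD-reference, proxy and annotation tables read from TSV", {
  ld_path <- tempfile(fileext = ".tsv")
  write.table(data.frame(id_a = "rs1", id_b = "rs2", r2 = 0.7), ld_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  px_path <- tempfile(fileext = ".tsv")
  write.table(data.frame(missing_id = "rs3", proxy_id = "rs4", r2 = 0.95), px_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- read_ld_reference(ld_path, px_path)
  cand <- data.frame(variant_id = c("rs1", "rs2"), pvalue = c(1e-10, 1e-9))
  expect_equal(clump(cand, ld, 0.5), "rs1")
  expect_equal(ld$proxies$proxy_id, "rs4")

  ann_path <- tempfile(fileext = ".tsv")
  write.table(data.frame(variant_id = "rs1", trait = "bmi", pvalue = 1e-9), ann_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_annotations(ann_path)
  expect_equal(ann$trait, "bmi")
})

test_that("annotation screen removes strongly associated variants only", {
  hs <- fixture_hset5()
  ann <- data.frame(variant_id = c("snp1", "snp2", "snp3"),
                    trait = c("bmi", "bmi", "education"),
                    pvalue = c(1e-9, 1e-6, 1e-10))
  screened <- screen_annotations(hs, ann, traits = c("bmi", "education"))
  expect_setequal(screened$variant_ids, c("snp2", "snp4", "snp5"))
  expect_equal(sort(screened$exclusion_log$reason),
               rep("annotation-screened", 2))

  # trait filter: only bmi considered
  bmi_only <- screen_annotations(hs, ann, traits = "bmi")
  expect_setequal(bmi_only$variant_ids, c("snp2", "snp3", "snp4", "snp5"))
})
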