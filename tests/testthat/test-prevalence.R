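mk_records <- function(n, n_iac = 0, n_iad = 0, n_both = 0, habitat = "h",
                       source_kind = "isolate", completeness = NA_real_,
                       contamination = NA_real_) {
  types <- c(rep("iac", n_iac), rep("iad", n_iad), rep("both", n_both),
             rep("none", n - n_iac - n_iad - n_both))
  data.frame(genome_id = sprintf("%s_%04d", habitat, seq_len(n)),
             habitat = habitat, order = "OrderA",
             completeness = completeness, contamination = contamination,
             source_kind = source_kind, degrader_type = types,
             stringsAsFactors = FALSE)
}

test_that("the quality filter applies inclusive boundaries", {
  rec <- data.frame(genome_id = c("a", "b", "c", "d"),
                    habitat = "h", order = "o",
                    completeness = c(90, 92, 95, 89.9),
                    contamination = c(5, 4, 5.5, 0),
                    source_kind = "MAG",
                    degrader_type = "none", stringsAsFactors = FALSE)
  kept <- filter_mags(rec)
  expect_equal(kept$genome_id, c("a", "b"))   # c: contamination gate; d: completeness
  expect_equal(kept$quality, c(90 - 25, 92 - 20))  # q = c - 5x: 65 and 72
  expect_equal(kept$quality_flag, c("pass", "pass"))
})

test_that("isolates without quality estimates pass with a flag", {
  rec <- mk_records(3, n_iac = 1)
  kept <- filter_mags(rec)
  expect_equal(nrow(kept), 3L)
  expect_true(all(kept$quality_flag == "assumed_pass"))
  expect_error(filter_mags(transform(rec, completeness = -1)), "negative")
})

test_that("the quality filter is idempotent", {
  set.seed(9)
  rec <- data.frame(genome_id = sprintf("m%03d", 1:40),
                    habitat = "h", order = "o",
                    completeness = runif(40, 80, 100),
                    contamination = runif(40, 0, 8),
                    source_kind = "MAG", degrader_type = "none",
                    stringsAsFactors = FALSE)
  once <- filter_mags(rec)
  twice <- filter_mags(once)
  expect_identical(once, twice)
})

test_that("prevalence percentages use half-up rounding to two decimals", {
  rec <- rbind(mk_records(544, n_iac = 40, n_iad = 20, n_both = 6, habitat = "plant_root"),
               mk_records(492, n_iad = 8, habitat = "wastewater"),
               mk_records(132, n_iac = 5, habitat = "plant_collections"),
               mk_records(100, habitat = "empty_none"))
  tab <- prevalence_by_stratum(rec, "habitat")
  get <- function(s, col) tab[tab$stratum == s, col]
  expect_equal(get("plant_root", "percent_positive"), 12.13)
  expect_equal(get("plant_root", "n_positive"), 66)
  expect_equal(get("wastewater", "percent_positive"), 1.63)
  expect_equal(get("plant_collections", "percent_positive"), 3.79)
  expect_equal(get("empty_none", "percent_positive"), 0)
  expect_equal(get("TOTAL", "n_screened"), 544 + 492 + 132 + 100)
  # positives partition into the three types
  expect_true(all(tab$n_positive == tab$n_iac + tab$n_iad + tab$n_both))
})

test_that("habitat strata partition the filtered records", {
  rec <- rbind(mk_records(25, n_iac = 3, habitat = "root"),
               mk_records(17, n_iad = 2, habitat = "soil"),
               mk_records(9, habitat = "marine"))
  tab <- prevalence_by_stratum(rec, "habitat")
  body <- tab[tab$stratum != "TOTAL", ]
  expect_equal(sum(body$n_screened), nrow(rec))
  expect_equal(sort(body$stratum), sort(unique(rec$habitat)))
})

test_that("stratification by taxonomic order works the same way", {
  rec <- mk_records(30, n_iac = 6)
  rec$order <- rep(c("Burkholderiales", "Rhizobiales"), 15)
  tab <- prevalence_by_stratum(rec, "order")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$n_screened[tab$stratum != "TOTAL"], c(15, 15))
})

test_that("unknown degrader types are rejected", {
  rec <- mk_records(5)
  rec$degrader_type[1] <- "mystery"
  expect_error(prevalence_by_stratum(rec), "mystery")
})

test_that("a synthetic survey returns exactly the planted prevalence", {
  strata <- data.frame(habitat = c("root", "soil"), n = c(12, 8),
                       prevalence = c(0.25, 0))
  sv <- generate_survey(strata, seed = 17, n_decoys = 12)
  expect_equal(nrow(sv$metadata), 20L)
  expect_equal(sum(sv$truth$intended_call != "none"), 3L)  # 12 * 0.25
  calls <- scan_genomes(sv$genomes)
  rec <- survey_records(calls, sv$metadata)
  kept <- filter_mags(rec)
  expect_equal(nrow(kept), 20L)  # quality drawn in passing ranges
  tab <- prevalence_by_stratum(kept, "habitat")
  expect_equal(tab$n_positive[tab$stratum == "root"], 3L)
  expect_equal(tab$n_positive[tab$stratum == "soil"], 0L)
  expect_equal(tab$percent_positive[tab$stratum == "root"], 25)
})

test_that("low-completeness genomes are removed by the filter, exactly", {
  strata <- data.frame(habitat = "root", n = 10, prevalence = 0)
  sv <- generate_survey(strata, seed = 23, n_decoys = 6,
                        completeness_range = c(95, 99))
  k <- 4
  sv$metadata$completeness[seq_len(k)] <- c(85, 88, 89.9, 70)
  kept <- filter_mags(sv$metadata)
  expect_equal(nrow(kept), 10 - k)
})

test_that("the long-format table matches the wide counts", {
  rec <- mk_records(50, n_iac = 5, n_iad = 3, n_both = 2)
  tab <- prevalence_by_stratum(rec, "habitat")
  lg <- prevalence_long(tab)
  expect_equal(sum(lg$n[lg$stratum == "h"]), 10L)
  expect_equal(lg$percent[lg$stratum == "h" & lg$degrader_type == "iac"], 10)
})
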