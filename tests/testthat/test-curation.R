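# A small resolved catalogue: 10 records over 4 taxa, two datasets.
curation_fixture <- function() {
  names10 <- c(rep("Aeolidia papillosa", 4), rep("Doris montereyensis", 3),
               rep("Hermissenda crassicornis", 2), "Zelentia punicea")
  cat <- merge_catalogues(list(
    toy_catalogue(6, "DIVES", "pmls", names = names10[1:6],
                  dates = paste0("200", 1:6, "-01-01")),
    toy_catalogue(4, "MUSEUM", "collection", names = names10[7:10],
                  dates = paste0("201", 1:4, "-06-15"))))
  cat$resolvedName <- cat$reportedName
  cat$phylum <- "Mollusca"; cat$class <- "Gastropoda"
  cat$order <- "Nudibranchia"
  cat$family <- vapply(strsplit(cat$reportedName, " "), function(x)
    paste0(x[1], "idae"), character(1))
  cat$genus <- vapply(strsplit(cat$reportedName, " "), `[`, character(1), 1)
  cat
}

test_that("taxon summaries group by canonical key and conserve counts", {
  cat <- curation_fixture()
  summ <- summarize_taxa(cat)
  expect_equal(nrow(summ), 4L)
  expect_equal(sum(summ$recordCount), 10L)
  aeo <- summ[summ$resolvedName == "Aeolidia papillosa", ]
  expect_equal(aeo$recordCount, 4L)
  expect_equal(aeo$firstDate, "2001-01-01")
  # a taxon reported by two datasets has both IDs and categories
  dor <- summ[summ$resolvedName == "Doris montereyensis", ]
  expect_equal(dor$reportingDatasetIDs, "DIVES;MUSEUM")
  expect_equal(dor$reportingCategories, "collection;pmls")
})

test_that("a single-record catalogue has firstDate == lastDate", {
  cat <- toy_catalogue(1, dates = "1999-09-09")
  cat$resolvedName <- cat$reportedName
  summ <- summarize_taxa(cat)
  expect_equal(nrow(summ), 1L)
  expect_equal(summ$firstDate, summ$lastDate)
})

test_that("phylum split partitions summaries, incertae catches the unplaced", {
  cat <- curation_fixture()
  summ <- summarize_taxa(cat)
  summ$phylum[1] <- "Cnidaria"
  summ$phylum[2] <- ""
  sheets <- split_by_phylum(summ)
  expect_setequal(names(sheets), c("Mollusca", "Cnidaria", "incertae"))
  expect_equal(sum(vapply(sheets, nrow, integer(1))), nrow(summ))
  expect_setequal(unlist(lapply(sheets, `[[`, "resolvedName")),
                  summ$resolvedName)
})

test_that("one sheet per group scales to a many-phyla checklist", {
  phyla <- paste0("Phylum", sprintf("%02d", 1:19))
  cat <- toy_catalogue(19, names = paste("Gena", paste0("morpha", letters[1:19])))
  cat$resolvedName <- cat$reportedName
  cat$phylum <- phyla
  sheets <- split_by_phylum(summarize_taxa(cat))
  expect_length(sheets, 19L)
})

test_that("sheet CSV round-trip is exact, including UTF-8 and commas", {
  cat <- curation_fixture()
  cat$reportedName[10] <- "Ägirella nörvegica"
  cat$resolvedName[10] <- "Ägirella nörvegica"
  summ <- summarize_taxa(cat)
  summ$curationNote[2] <- 'tricky, "quoted", comma-laden note'
  summ$authority[3] <- "(Müller, 1776)"
  dir <- withr::local_tempdir()
  write_sheets(split_by_phylum(summ), dir)
  back <- read_sheets(dir)
  ri <- reintegrate_sheets(back, summ)
  expect_equal(nrow(diff_summaries(summ, ri$summaries)), 0L)
  expect_equal(nrow(ri$proposals), 0L)
  expect_setequal(ri$summaries$resolvedName, summ$resolvedName)
  expect_equal(sort(ri$summaries$curationNote), sort(summ$curationNote))
})

test_that("preferredName edits become proposals; note edits apply directly", {
  cat <- curation_fixture()
  cat$resolvedName[cat$reportedName == "Zelentia punicea"] <-
    "Cadlina luteomarginata"
  summ <- summarize_taxa(cat)
  sheets <- split_by_phylum(summ)
  hit <- sheets$Mollusca$resolvedName == "Cadlina luteomarginata"
  sheets$Mollusca$preferredName[hit] <- "Cadlina klasmalmbergi"
  sheets$Mollusca$editReason[hit] <- "conceptChange"
  sheets$Mollusca$curationNote[hit] <- "split into four species"
  ri <- reintegrate_sheets(sheets, summ)
  expect_equal(nrow(ri$proposals), 1L)
  expect_equal(ri$proposals$reportedName, "Cadlina luteomarginata")
  expect_equal(ri$proposals$preferredName, "Cadlina klasmalmbergi")
  expect_equal(ri$proposals$reason, "conceptChange")
  expect_true("Cadlina klasmalmbergi" %in% ri$summaries$resolvedName)
  expect_true("split into four species" %in% ri$summaries$curationNote)
})

test_that("untouched sheets reintegrate to identity with no proposals", {
  summ <- summarize_taxa(curation_fixture())
  ri <- reintegrate_sheets(split_by_phylum(summ), summ)
  expect_equal(nrow(ri$proposals), 0L)
  expect_equal(nrow(diff_summaries(summ, ri$summaries)), 0L)
})

test_that("edits to computed columns are ignored on re-import", {
  summ <- summarize_taxa(curation_fixture())
  sheets <- split_by_phylum(summ)
  sheets$Mollusca$recordCount <- 999L
  sheets$Mollusca$reportingCategories <- "fabricated"
  ri <- reintegrate_sheets(sheets, summ)
  expect_equal(nrow(diff_summaries(summ, ri$summaries)), 0L)
  expect_equal(ri$summaries$recordCount, summ$recordCount)
})

test_that("key-row damage and reason-less renames fail naming the sheet", {
  summ <- summarize_taxa(curation_fixture())
  sheets <- split_by_phylum(summ)
  broken <- sheets
  broken$Mollusca <- broken$Mollusca[-1, ]
  expect_error(reintegrate_sheets(broken, summ), "Mollusca.*deleted")
  duped <- sheets
  duped$Mollusca <- rbind(duped$Mollusca, duped$Mollusca[1, ])
  expect_error(reintegrate_sheets(duped, summ), "duplicated")
  noreason <- sheets
  noreason$Mollusca$preferredName[1] <- "Alia res"
  expect_error(reintegrate_sheets(noreason, summ), "reason")
})

test_that("summary diffs classify renames, edits and additions", {
  a <- summarize_taxa(curation_fixture())
  expect_equal(nrow(diff_summaries(a, a)), 0L)

  b <- a
  b$resolvedName[1] <- "Renamia mutata"
  b$taxonKey[1] <- canonical_key("Renamia mutata")
  d <- diff_summaries(a, b)
  expect_equal(d$kind, "renamedTaxon")
  expect_equal(d$before, a$resolvedName[1])
  expect_equal(d$after, "Renamia mutata")

  b2 <- a[-2, ]
  d2 <- diff_summaries(a, b2)
  expect_equal(d2$kind, "removedTaxon")
  d3 <- diff_summaries(b2, a)
  expect_equal(d3$kind, "addedTaxon")

  b4 <- a
  b4$authority[3] <- "(Other, 1999)"
  b4$curationNote[4] <- "checked"
  d4 <- diff_summaries(a, b4)
  expect_setequal(d4$kind, c("changedAuthority", "changedNote"))
})

test_that("a k-edit script yields exactly k diff entries", {
  set.seed(31)
  base <- summarize_taxa(toy_catalogue(
    30, names = paste("Generis", sprintf("forma%02d", 1:30)),
    dates = paste0(1981:2010, "-01-01")))
  for (trial in 1:5) {
    b <- base
    k_rename <- sample(0:3, 1); k_note <- sample(0:3, 1)
    idx <- sample(nrow(b), k_rename + k_note)
    ren <- idx[seq_len(k_rename)]
    if (k_rename > 0) {
      b$resolvedName[ren] <- paste("Novata", paste0("species", ren))
      b$taxonKey[ren] <- canonical_key(b$resolvedName[ren])
    }
    if (k_note > 0)
      b$curationNote[idx[k_rename + seq_len(k_note)]] <- "edited"
    d <- diff_summaries(base, b)
    expect_equal(nrow(d), k_rename + k_note)
    expect_equal(sum(d$kind == "renamedTaxon"), k_rename)
    expect_equal(sum(d$kind == "changedNote"), k_note)
  }
})

test_that("zero-edit pipelines converge in a single pass", {
  fx <- generate_fixture(fixture_config(
    seed = 21, exclusive = c(pmls = 4, crowd = 3), shared = 3,
    records_target = c(pmls = 30, crowd = 15)))
  out <- run_to_fixed_point(fx$sources, fx$truth$resolution,
                            fx$truth$patches, fx$truth$area, fx$backbone)
  expect_equal(out$iterations, 1L)
  expect_equal(nrow(out$history[[1]]), 0L)
  expect_equal(sum(out$summaries$recordCount), nrow(out$catalogue))
})

test_that("a single scripted rename converges on the second pass", {
  fx <- generate_fixture(fixture_config(
    seed = 22, exclusive = c(pmls = 4, crowd = 3), shared = 3,
    records_target = c(pmls = 30, crowd = 15)))
  target <- fx$truth$taxa$name[1]
  editor <- function(sheets, iteration) {
    for (ph in names(sheets)) {
      hit <- sheets[[ph]]$resolvedName == target
      if (any(hit)) {
        sheets[[ph]]$preferredName[hit] <- "Revisa concepta"
        sheets[[ph]]$editReason[hit] <- "conceptChange"
      }
    }
    sheets
  }
  n_rules <- nrow(fx$truth$resolution)
  out <- run_to_fixed_point(fx$sources, fx$truth$resolution,
                            fx$truth$patches, fx$truth$area, fx$backbone,
                            curation_fun = editor)
  expect_equal(out$iterations, 2L)
  expect_equal(nrow(out$history[[1]]), 1L)
  expect_equal(nrow(out$history[[2]]), 0L)
  expect_true("Revisa concepta" %in% out$summaries$resolvedName)
  # monotone knowledge: the resolution table grew by exactly the proposal
  expect_equal(nrow(out$resolution), n_rules + 1L)
  expect_true(all(fx$truth$resolution$reportedName %in%
                  out$resolution$reportedName))
})

test_that("an oscillating editor fails at max_iter with a residual diff", {
  fx <- generate_fixture(fixture_config(
    seed = 23, exclusive = c(pmls = 4, crowd = 3), shared = 3,
    records_target = c(pmls = 30, crowd = 15)))
  a_name <- fx$truth$taxa$name[1]
  b_name <- "Oscilla perpetua"
  editor <- function(sheets, iteration) {
    for (ph in names(sheets)) {
      hitA <- sheets[[ph]]$resolvedName == a_name
      hitB <- sheets[[ph]]$resolvedName == b_name
      if (any(hitA)) {
        sheets[[ph]]$preferredName[hitA] <- b_name
        sheets[[ph]]$editReason[hitA] <- "conceptChange"
      }
      if (any(hitB)) {
        sheets[[ph]]$preferredName[hitB] <- a_name
        sheets[[ph]]$editReason[hitB] <- "conceptChange"
      }
    }
    sheets
  }
  expect_error(
    suppressWarnings(run_to_fixed_point(
      fx$sources, fx$truth$resolution, fx$truth$patches, fx$truth$area,
      fx$backbone, curation_fun = editor, max_iter = 4L)),
    "no fixed point.*residual")
})
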