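simple_catalog <- function() {
  make_catalog(data.frame(
    pathway = c("acid phosphatase", "ferrous oxidation", "CO oxidation"),
    cycle = c("P", "Fe", "C"),
    marker_id = c("PF03767", "PF00210", "K03520"),
    db = c("Pfam", "Pfam", "KEGG"),
    gene_symbol = c("", "", "coxL"), stringsAsFactors = FALSE))
}

test_that("contig annotation reader parses, filters and validates", {
  f <- contig_tsv(c(
    crow("c1", "S01", 1400, "PF03767", "Bacteria", "Actinobacteria",
         "Actinomycetia", "Corynebacteriales", "Mycobacteriaceae",
         "Mycobacterium"),
    crow("c2", "S01", 300, "PF00210", "Bacteria"),
    crow("c3", "S02", 800, "", "Bacteria")))
  expect_message(tab <- read_contig_annotations(f), "dropped 1 contig")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$marker_ids[[1]], "PF03767")
  expect_equal(tab$genus[1], "Mycobacterium")
  expect_equal(tab$marker_ids[[2]], character())
  expect_equal(tab$phylum[2], "UNASSIGNED")

  # genus present but family absent breaks the lineage prefix rule
  f2 <- contig_tsv(paste(c("c1", "S01", 900, "", "Bacteria", "Actinobacteria",
                           "Actinomycetia", "Corynebacteriales", "",
                           "Mycobacterium"), collapse = "\t"))
  expect_error(read_contig_annotations(f2), "row 1.*lineage prefix")

  # missing column and non-integer length are rejected
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig_id\tsample_id\tlength_bp", "c1\tS01\t500"), f3)
  expect_error(read_contig_annotations(f3), "lacks column")
  f4 <- contig_tsv(crow("c1", "S01", "12.5x", "", "Bacteria"))
  expect_error(read_contig_annotations(f4), "row 1.*length_bp")
})

test_that("marker counts handle multi-marker contigs and empty tables", {
  cat <- simple_catalog()
  f <- contig_tsv(c(
    crow("c1", "S01", 900, "PF03767;PF00210", "Bacteria"),
    crow("c2", "S01", 900, "PF03767;PF03767", "Bacteria"),
    crow("c3", "S01", 900, "", "Bacteria")))
  m <- read_contig_annotations(f) |> marker_count_matrix(cat)
  # c1 counts once for each of its two pathways; c2 once despite two hits
  expect_equal(m["S01", "acid phosphatase"], 2L, ignore_attr = TRUE)
  expect_equal(m["S01", "ferrous oxidation"], 1L, ignore_attr = TRUE)
  expect_equal(m["S01", "CO oxidation"], 0L, ignore_attr = TRUE)

  empty <- contig_tsv(character())
  m0 <- read_contig_annotations(empty) |> marker_count_matrix(cat)
  expect_equal(dim(m0), c(0L, 3L))
  expect_setequal(colnames(m0), cat$entries$pathway)
})

test_that("a replaced KO accession is counted for its Pfam substitute's pathway", {
  cat <- builtin_catalog()
  f <- contig_tsv(c(
    crow("c1", "S01", 900, "K14084", "Bacteria"),   # replaced KO
    crow("c2", "S01", 900, "PF06253", "Bacteria"))) # its Pfam substitute
  m <- read_contig_annotations(f) |> marker_count_matrix(cat)
  expect_equal(m["S01", "methanogenesis"], 2L, ignore_attr = TRUE)
})

test_that("placeholder catalog entries are never matched", {
  cat <- builtin_catalog()
  ph_id <- cat$entries$marker_id[cat$entries$gene_symbol %in% "coxL"]
  f <- contig_tsv(crow("c1", "S01", 900, ph_id, "Bacteria"))
  m <- read_contig_annotations(f) |> marker_count_matrix(cat)
  expect_equal(sum(m), 0)
})

test_that("pooled proportions use all contigs and differ from per-sample means", {
  cat <- simple_catalog()
  rows <- c(
    sprintf("h%d\tS01\t900\tK03520\tBacteria\t\t\t\t\t", 1:3),
    sprintf("n%d\tS01\t900\t\tBacteria\t\t\t\t\t", 1:7),
    sprintf("h%d\tS02\t900\tK03520\tBacteria\t\t\t\t\t", 4),
    sprintf("n%d\tS02\t900\t\tBacteria\t\t\t\t\t", 8:36))
  tab <- read_contig_annotations(contig_tsv(rows))
  pr <- pathway_proportions(tab, cat)
  # (10 contigs, 3 hits) and (30 contigs, 1 hit)
  expect_equal(pr$per_sample["S01", "CO oxidation"], 0.30)
  expect_equal(pr$per_sample["S02", "CO oxidation"], 1 / 30)
  expect_equal(pr$pooled[["CO oxidation"]], 4 / 40)
  expect_false(isTRUE(all.equal(pr$pooled[["CO oxidation"]],
                                mean(pr$per_sample[, "CO oxidation"]))))
  expect_true(all(pr$per_sample >= 0 & pr$per_sample <= 1))
})

test_that("assignment rate is the assigned fraction of marker contigs, NA when empty", {
  cat <- simple_catalog()
  rows <- c(
    crow("c1", "S01", 900, "PF03767", "Bacteria", "Proteobacteria", "Alpha",
         "Rhizobiales", "Bradyrhizobiaceae", "Bradyrhizobium"),
    crow("c2", "S01", 900, "PF03767", "Bacteria"),
    crow("c3", "S01", 900, "PF03767", "Bacteria"),
    crow("c4", "S02", 900, "PF03767", "Bacteria"),
    crow("c5", "S02", 900, "PF00210", "Bacteria", "Proteobacteria", "Alpha",
         "Rhizobiales", "Bradyrhizobiaceae", "Bradyrhizobium"))
  tab <- read_contig_annotations(contig_tsv(rows))
  ar <- assignment_rate(tab, cat, rank = "genus")
  expect_equal(ar[["acid phosphatase"]], 0.25)
  expect_equal(ar[["ferrous oxidation"]], 1.0)
  expect_true(is.na(ar[["CO oxidation"]]))
  # at kingdom rank everything is assigned
  ark <- assignment_rate(tab, cat, rank = "kingdom")
  expect_equal(ark[["acid phosphatase"]], 1.0)
})

test_that("function-taxon counts conserve marker totals and ignore row order", {
  cat <- simple_catalog()
  rows <- c(
    crow("c1", "S01", 900, "PF03767", "Bacteria", "P1", "C1", "O1", "F1", "G1"),
    crow("c2", "S01", 900, "PF03767", "Bacteria", "P1", "C1", "O1", "F1", "G1"),
    crow("c3", "S02", 900, "PF03767", "Bacteria"),
    crow("c4", "S02", 900, "PF03767;PF00210", "Bacteria", "P1", "C1", "O1",
         "F1", "G1"),
    crow("c5", "S02", 900, "K03520", "Bacteria", "P1", "C1", "O1", "F1", "G2"))
  tab <- read_contig_annotations(contig_tsv(rows))
  ftc <- function_taxon_counts(tab, cat, rank = "genus")
  w <- function(p, t) {
    r <- ftc$counts[ftc$counts$pathway == p & ftc$counts$taxon == t, "weight"]
    if (length(r) == 0) 0L else r
  }
  expect_equal(w("acid phosphatase", "G1"), 3L)
  expect_equal(ftc$unassigned[["acid phosphatase"]], 1L)
  # c4 carries markers of two pathways: weight 1 to each with the same taxon
  expect_equal(w("ferrous oxidation", "G1"), 1L)
  expect_equal(w("CO oxidation", "G2"), 1L)

  # conservation against the pooled count matrix
  pooled <- colSums(marker_count_matrix(tab, cat))
  per_path <- tapply(ftc$counts$weight, ftc$counts$pathway, sum, default = 0L)
  for (p in names(pooled)) {
    tot <- (if (p %in% names(per_path)) per_path[[p]] else 0L) +
      ftc$unassigned[[p]]
    expect_equal(tot, pooled[[p]], ignore_attr = TRUE)
  }

  # permuting input rows changes nothing
  perm <- withr::with_seed(7, sample(nrow(tab)))
  tab2 <- tab[perm, ]
  ftc2 <- function_taxon_counts(tab2, cat, rank = "genus")
  expect_equal(ftc2$counts, ftc$counts)
  expect_equal(ftc2$unassigned, ftc$unassigned)
  expect_equal(marker_count_matrix(tab2, cat), marker_count_matrix(tab, cat))
})
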