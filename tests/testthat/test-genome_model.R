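test_that("GTF parsing converts coordinates and assigns strand-aware TSS", {
  ann <- toy_annotation()
  # + strand: TSS is the 0-based start (GTF start 100 -> internal 99)
  expect_equal(unname(ann$tss["gplus"]), 99)
  # - strand: TSS is the last covered base (GTF end 5400 -> internal 5399)
  expect_equal(unname(ann$tss["gminus"]), 5399)
  # canonical transcript = largest summed exon length; TSS taken from it
  expect_equal(unname(ann$canonical["gtwo"]), "t_long")
  expect_equal(unname(ann$tss["gtwo"]), 9500)
})

test_that("malformed GTF lines are reported with their line number", {
  path <- tempfile(fileext = ".gtf")
  lines <- toy_gtf_lines()
  lines[3] <- "chr1\tbroken line with too few fields"
  writeLines(lines, path)
  expect_error(parse_annotation(path), "line 3")
})

test_that("exons outside transcript bounds fail validation", {
  path <- tempfile(fileext = ".gtf")
  at <- 'gene_id "g"; transcript_id "t";'
  writeLines(c(
    paste("chr1", "t", "gene", 100, 200, ".", "+", ".", 'gene_id "g";', sep = "\t"),
    paste("chr1", "t", "transcript", 100, 200, ".", "+", ".", at, sep = "\t"),
    paste("chr1", "t", "exon", 100, 300, ".", "+", ".", at, sep = "\t")
  ), path)
  expect_error(parse_annotation(path), "outside transcript")
})

test_that("annotation round-trips through write_gtf with identical TSS", {
  ann <- toy_annotation()
  out <- tempfile(fileext = ".gtf")
  write_gtf(ann, out)
  ann2 <- parse_annotation(out, chrom_sizes = ann$chrom_sizes)
  expect_identical(ann$tss, ann2$tss)
  expect_identical(ann$canonical, ann2$canonical)
})

test_that("proximal/distal classification follows the inclusive 1 kb rule", {
  ann <- toy_annotation()
  # TSS gplus = 99 lies inside [50, 800) -> proximal
  expect_equal(classify_proximal_distal(toy_peak("chr1", 50, 800), ann), "proximal")
  # nearest TSS far beyond the boundary -> distal
  expect_equal(classify_proximal_distal(toy_peak("chr1", 2899, 3899), ann), "distal")
  # boundary distance exactly 1000 bp -> proximal ("within 1 kb" inclusive);
  # one bp further -> distal (TSS gplus at 99, peak start 1099 vs 1100)
  expect_equal(classify_proximal_distal(toy_peak("chr1", 1099, 1200), ann), "proximal")
  expect_equal(classify_proximal_distal(toy_peak("chr1", 1100, 1200), ann), "distal")
  # chromosome with no annotated gene -> distal, no error
  expect_equal(classify_proximal_distal(toy_peak("chrZ", 0, 100), ann), "distal")
})

test_that("proximal/distal is invariant to annotation row order", {
  ann <- toy_annotation()
  set.seed(7)
  peaks <- do.call(rbind, lapply(1:20, function(i) {
    s <- sample(0:20000, 1); toy_peak("chr1", s, s + 500, id = paste0("p", i))
  }))
  base <- classify_proximal_distal(peaks, ann)
  perm <- ann
  o <- sample(nrow(perm$genes))
  perm$genes <- perm$genes[o, ]
  perm$tss <- perm$tss[sample(length(perm$tss))]
  expect_equal(classify_proximal_distal(peaks, perm), base)
})

test_that("feature classification is total and follows summit priority", {
  ann <- toy_annotation()
  # summit within 1 kb of TSS -> promoter-TSS beats exon
  r <- classify_feature(toy_peak("chr1", 100, 300, summit = 150), ann)
  expect_equal(r$label, "promoter-TSS")
  # summit in an exon far from any TSS (t_long exon 9500..10000, TSS 9500)
  r <- classify_feature(toy_peak("chr2", 10500, 10700, summit = 10600), ann)
  expect_equal(r$label, "intergenic")
  # summit 50 kb from any gene -> intergenic
  r <- classify_feature(toy_peak("chr1", 50000, 50500, summit = 50200), ann)
  expect_equal(r$label, "intergenic")
  # intron of gplus between exons [99,200) and [299,400): position 250 is
  # > 1 kb from no TSS (TSS 99 at distance 151) -> promoter wins; use gminus
  # intron instead: exons [5099,5200) & [5299,5400), TSS 5399, pos 5250 is
  # 149 bp from TSS -> promoter again. Build a dedicated wide gene:
  path <- tempfile(fileext = ".gtf")
  at <- 'gene_id "gw"; transcript_id "tw";'
  writeLines(c(
    paste("chr1", "t", "gene", 1, 30000, ".", "+", ".", 'gene_id "gw";', sep = "\t"),
    paste("chr1", "t", "transcript", 1, 30000, ".", "+", ".", at, sep = "\t"),
    paste("chr1", "t", "exon", 1, 1000, ".", "+", ".", at, sep = "\t"),
    paste("chr1", "t", "exon", 20000, 30000, ".", "+", ".", at, sep = "\t")
  ), path)
  wide <- parse_annotation(path, chrom_sizes = c(chr1 = 1e6))
  r <- classify_feature(toy_peak("chr1", 10000, 10500, summit = 10200), wide)
  expect_equal(r$label, "intron")
  expect_equal(r$intron_ordinal, 1L)
  r <- classify_feature(toy_peak("chr1", 25000, 25500, summit = 25200), wide)
  expect_equal(r$label, "exon")
  # exactly one label for any peak
  set.seed(11)
  peaks <- do.call(rbind, lapply(1:30, function(i) {
    s <- sample(0:40000, 1); toy_peak("chr1", s, s + 200, id = paste0("p", i))
  }))
  labs <- classify_feature(peaks, wide)$label
  expect_true(all(labs %in% c("promoter-TSS", "exon", "intron", "intergenic")))
  expect_length(labs, 30)
})

test_that("intron ordinal is 1-based and counted from the TSS side", {
  # exons [99,200) and [299,400): the gap [200,299) is intron 1 on both
  # strands of a two-exon transcript
  expect_equal(intron_ordinal(250, c(99, 299), c(200, 400), "+"), 1L)
  expect_equal(intron_ordinal(250, c(99, 299), c(200, 400), "-"), 1L)
  # exonic position -> NA
  expect_true(is.na(intron_ordinal(150, c(99, 299), c(200, 400), "+")))
  # single exon: never intronic
  expect_true(is.na(intron_ordinal(150, 99, 400, "+")))
  # three exons discriminate the strands: gap between exon 1 and 2 is
  # intron 1 on + but intron 2 counted from the - strand TSS
  es <- c(0, 300, 600); ee <- c(100, 400, 700)
  expect_equal(intron_ordinal(200, es, ee, "+"), 1L)
  expect_equal(intron_ordinal(200, es, ee, "-"), 2L)
  expect_equal(intron_ordinal(500, es, ee, "-"), 1L)
  # ordinal always within [1, n_exons - 1]
  for (pos in c(150, 250, 450, 550)) {
    o <- intron_ordinal(pos, es, ee, "-")
    if (!is.na(o)) expect_true(o >= 1 && o <= 2)
  }
})

test_that("summit-TSS distance is absolute and requires one chromosome", {
  expect_equal(peak_gene_distance(500000, 1400000), 900000)
  expect_equal(peak_gene_distance(1234, 1234), 0)
  expect_equal(peak_gene_distance(100, 1100100), 1100000)
  expect_error(peak_gene_distance(1, 2, "chr1", "chr2"), "different chromosomes")
})
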