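test_that("link test reproduces closed-form Pearson cases", {
  x <- 1:6
  lt <- link_test(x, 2 * x + 1)
  expect_equal(lt$r, 1)
  expect_equal(lt$p, 0)
  expect_equal(link_test(x, -x)$r, -1)
  # hand case: r by the direct summation formula
  # (sum of cross-deviations 14.5 over sqrt(17.5 * 17.5))
  y <- c(2, 1, 4, 3, 6, 5)
  lt2 <- link_test(x, y)
  expect_equal(lt2$r, pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(lt2$r, 14.5 / 17.5, tolerance = 1e-12)
  tstat <- lt2$r * sqrt(4 / (1 - lt2$r^2))
  expect_equal(lt2$p, 2 * pt(-abs(tstat), df = 4), tolerance = 1e-12)
  # constant vectors are rejected with a reason, not an error
  lt3 <- link_test(rep(3, 6), x)
  expect_true(is.na(lt3$r))
  expect_equal(lt3$reason, "constant vector")
  expect_error(link_test(1:5, 1:6), "length mismatch")
  expect_error(link_test(1:2, 2:1), "at least 3")
})

test_that("candidate pairs respect the 1 Mb same-chromosome window", {
  ann <- toy_annotation()  # TSS: gplus 99, gminus 5399 (chr1); gtwo 9500 (chr2)
  pks <- data.frame(peak_id = c("a", "b", "c"),
                    chrom = c("chr1", "chr1", "chr2"),
                    summit = c(900099, 1200100, 9500),
                    stringsAsFactors = FALSE)
  pairs <- candidate_pairs(pks, ann)
  # peak a: 900 kb from gplus -> included; 894.7 kb from gminus -> included
  expect_setequal(pairs$gene_id[pairs$peak_id == "a"], c("gplus", "gminus"))
  # peak b: 1.2 Mb from gplus -> excluded entirely on chr1
  expect_false("b" %in% pairs$peak_id)
  # peak c sits on gtwo's TSS; chr1 genes are on another chromosome
  expect_identical(pairs$gene_id[pairs$peak_id == "c"], "gtwo")
  expect_equal(pairs$distance[pairs$peak_id == "c"], 0L)
})

test_that("link selection applies strict r and p thresholds with a stable order", {
  scored <- data.frame(
    peak_id = c("p2", "p1", "p3", "p1"),
    gene_id = c("g1", "g2", "g3", "g1"),
    chrom = "chr1", distance = 1000L,
    r = c(0.99, 0.86, -0.95, 0.7),
    p = c(0.0005, 0.029, 0.004, 0.2),
    sign = c("positive", "positive", "negative", "positive"),
    stringsAsFactors = FALSE)
  sel <- select_links(scored)
  # r = 0.86 with p = 0.029 (the n = 6 regime) fails the p < 0.01 clause
  expect_setequal(paste(sel$peak_id, sel$gene_id), c("p2 g1", "p3 g3"))
  expect_equal(sel$peak_id, sort(sel$peak_id))
  expect_equal(sel$sign[sel$peak_id == "p3"], "negative")
})

test_that("scored pairs carry the correlation of signal against abundance", {
  sig <- matrix(c(1, 2, 3, 4, 5, 6, 6, 5, 4, 3, 2, 1), 2, 6, byrow = TRUE,
                dimnames = list(c("pk1", "pk2"), paste0("s", 1:6)))
  ab <- matrix(c(2, 4, 6, 8, 10, 12), 1, 6,
               dimnames = list("g1", paste0("s", 1:6)))
  pairs <- data.frame(peak_id = c("pk1", "pk2"), gene_id = "g1",
                      chrom = "chr1", distance = 1L, stringsAsFactors = FALSE)
  sc <- score_links(pairs, sig, ab)
  expect_equal(sc$r, c(1, -1))
  expect_equal(sc$sign, c("positive", "negative"))
})

test_that("top gene lists deduplicate by best link and sort by p then |r|", {
  links <- data.frame(
    peak_id = c("p1", "p2", "p3", "p4"),
    gene_id = c("gA", "gA", "gB", "gC"),
    r = c(0.97, 0.99, 0.95, -0.96),
    p = c(0.005, 0.001, 0.003, 0.003),
    stringsAsFactors = FALSE)
  diff <- data.frame(feature = paste0("p", 1:4),
                     direction = c("hyper", "hyper", "hyper", "hypo"),
                     stringsAsFactors = FALSE)
  top <- top_peak_genes(links, diff, k = 100)
  # gA appears once, with its best (p = 0.001) link
  expect_equal(top$hyper$gene_id, c("gA", "gB"))
  expect_equal(top$hyper$p, c(0.001, 0.003))
  expect_equal(top$hypo$gene_id, "gC")
  # k truncates
  top2 <- top_peak_genes(links, diff, k = 1)
  expect_equal(nrow(top2$hyper), 1)
  expect_equal(top2$hyper$gene_id, "gA")
  # sort oracle on distinct p
  l3 <- data.frame(peak_id = paste0("q", 1:3), gene_id = paste0("g", 1:3),
                   r = c(0.93, 0.99, 0.95), p = c(0.008, 0.001, 0.004),
                   stringsAsFactors = FALSE)
  d3 <- data.frame(feature = paste0("q", 1:3), direction = "hyper",
                   stringsAsFactors = FALSE)
  expect_equal(top_peak_genes(l3, d3)$hyper$gene_id,
               l3$gene_id[order(l3$p)])
})

test_that("distance decay conserves links and bins correctly", {
  links <- data.frame(distance = c(5e4, 9e4, 2e4, 9.5e5),
                      sign = c("positive", "positive", "negative", "negative"),
                      peak_direction = "hyper", stringsAsFactors = FALSE)
  h <- distance_decay(links)
  expect_equal(sum(h$count), nrow(links))
  bin1 <- h[h$bin_start == 0, ]
  expect_equal(sum(bin1$count), 3)
  expect_equal(sum(h$count[h$bin_start == 9e5]), 1)
  # all links below 100 kb -> all mass in the first bin
  h2 <- distance_decay(links[links$distance < 1e5, ])
  expect_equal(sum(h2$count[h2$bin_start > 0]), 0)
  # empty link set -> all-zero histogram
  h3 <- distance_decay(links[0, ])
  expect_true(all(h3$count == 0))
  # uniform distances spread uniformly within multinomial error
  set.seed(31)
  lu <- data.frame(distance = runif(5000, 0, 1e6),
                   sign = "positive", peak_direction = "hyper",
                   stringsAsFactors = FALSE)
  hu <- distance_decay(lu)
  cnt <- hu$count[hu$sign == "positive"]
  expect_equal(sum(cnt), 5000)
  expect_true(all(abs(cnt - 500) < 5 * sqrt(500)))
})
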