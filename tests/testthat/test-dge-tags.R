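adapter <- "TCGTATGCCGTCTTCTGCTTG"

test_that("adapter trimming returns the tag for an exact suffix match", {
  tag <- "GATCACGTACGTACGTA"  # 17 nt
  read <- substr(paste0(tag, adapter), 1, 36)
  expect_equal(trim_adapter(read, adapter), tag)
})

test_that("reads with no adapter-like suffix fall back to the first 18 nt", {
  read <- strrep("AC", 18)  # 36 nt, nothing adapter-like
  expect_equal(trim_adapter(read, "GGGTTTGGGTTTGGGTTT"), substr(read, 1, 18))
})

test_that("position-weighted cost accepts late mismatches and rejects early ones", {
  # aligned region of l = 16: mismatches at offsets {2,3} cost
  # 14/16 + 13/16 = 1.6875 > 1 (rejected); a single mismatch at offset 14
  # costs 2/16 = 0.125 <= 1 (accepted)
  adpt16 <- "GCGTATGACGTCTTCA"
  tag16 <- "ATCAATCCTGAAGCTA"
  flip <- function(s, i) {
    ch <- strsplit(s, "")[[1]]
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  early <- paste0(tag16, flip(flip(adpt16, 3), 4))   # offsets 2,3 (0-based)
  late <- paste0(tag16, flip(adpt16, 15))            # offset 14 (0-based)
  expect_equal(trim_adapter(late, adpt16), tag16)
  expect_equal(trim_adapter(early, adpt16), oracle_trim(early, adpt16))
  expect_false(identical(trim_adapter(early, adpt16), tag16))
})

test_that("trimming agrees with the direct cost-formula oracle on random reads", {
  withr::with_seed(41, {
    reads <- vapply(1:150, function(i) {
      tag_len <- sample(10:18, 1)
      tag <- random_dna(tag_len)
      rd <- substr(paste0(tag, adapter), 1, 36)
      if (i %% 3 == 0) {  # inject up to 3 errors anywhere
        ch <- strsplit(rd, "")[[1]]
        for (e in seq_len(sample(3, 1))) {
          j <- sample(nchar(rd), 1)
          ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
        }
        rd <- paste(ch, collapse = "")
      }
      if (i %% 7 == 0) rd <- random_dna(36)
      rd
    }, "")
  })
  got <- trim_adapter(reads, adapter)
  want <- vapply(reads, oracle_trim, "", adapter = adapter,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("a short transcript yields one window spanning it entirely", {
  tx <- tiny_transcriptome(paste0("AAAGATCTTT", strrep("A", 50)))
  win <- build_reduced_reference(tx, flank = 36)
  expect_equal(nrow(win), 1)
  expect_equal(win$site_start, 3)
  expect_equal(win$window_start, 0)
  expect_equal(win$site_offset, 3)
  expect_true(win$is_3prime_most)
  expect_equal(win$window_sequence, substr(tx$sequence, 1, 3 + 4 + 36))
})

test_that("only the last DpnII site is 3'-most and windows count GATC occurrences", {
  s <- paste0(strrep("A", 3), "GATC", strrep("C", 13), "GATC", strrep("T", 30))
  tx <- tiny_transcriptome(s)
  win <- build_reduced_reference(tx)
  expect_equal(win$site_start, c(3, 20))
  expect_equal(win$is_3prime_most, c(FALSE, TRUE))
  big <- generate_transcriptome(80, seed = 19)
  wins <- build_reduced_reference(big)
  expect_equal(nrow(wins),
               sum(stringr::str_count(big$sequence, stringr::fixed("GATC"))))
})

test_that("expected tag extraction anchors at the 3'-most site", {
  expect_true(is.na(extract_expected_tag(strrep("ACT", 30))))
  s <- paste0(strrep("C", 10), "GATC", strrep("A", 13))
  expect_equal(extract_expected_tag(s, 17), paste0("GATC", strrep("A", 13)))
  expect_true(is.na(extract_expected_tag(s, 18)))  # only 13 nt downstream
  two <- paste0(strrep("C", 5), "GATC", strrep("T", 31), "GATC",
                strrep("A", 20))
  got <- extract_expected_tag(two, 17)
  expect_equal(got, substr(two, 41, 57))
  expect_equal(substr(got, 1, 4), "GATC")
})

test_that("error-free unique tags map unambiguously with zero mismatches", {
  tx <- generate_transcriptome(30, dpn_site_prob = 1, seed = 43)
  truth <- make_truth(tx, n_de = 0, seed = 43)
  nm <- noise_model(seq_error_rate = 0, library_sizes = rep(2000L, 2))
  dge <- generate_dge_reads(truth, tx, nm, n_samples = 2, seed = 43)
  win <- build_reduced_reference(tx)
  trimmed <- lapply(dge$reads, trim_adapter, adapter = adapter)
  res <- count_tags(trimmed, win)
  expect_equal(res$stats$unambiguous, res$stats$total)
  expect_equal(res$stats$mm0, res$stats$total)
  # per-gene counts equal the generator's sampling tally
  tally <- tapply(dge$tag_tally[["C1"]],
                  tx$gene_symbol[match(names(dge$tag_tally[["C1"]]),
                                       tx$transcript_id)], sum)
  cnt <- tapply(res$counts$C1, res$counts$gene_symbol, sum)
  expect_equal(as.vector(cnt[names(tally)]), as.vector(tally))
})

test_that("a tag planted in two genes' windows is ambiguous and uncounted", {
  tagseq <- paste0("GATC", "ACGTACGTACGTA")  # 17 nt
  tx <- tiny_transcriptome(c(
    paste0(random_dna(30, seed = 1), tagseq, random_dna(10, seed = 2)),
    paste0(random_dna(45, seed = 3), tagseq, random_dna(10, seed = 4))))
  win <- build_reduced_reference(tx)
  res <- count_tags(list(s1 = tagseq), win)
  expect_equal(res$stats$ambiguous, 1)
  expect_equal(res$stats$unambiguous, 0)
  expect_true(all(res$counts$s1 == 0))
})

test_that("mismatch-class tallies equal the brute-force all-window oracle", {
  tx <- generate_transcriptome(25, dpn_site_prob = 1,
                               length_range = c(100, 200), seed = 47)
  truth <- make_truth(tx, n_de = 0, seed = 47)
  nm <- noise_model(seq_error_rate = 0.02, library_sizes = rep(400L, 2))
  dge <- generate_dge_reads(truth, tx, nm, n_samples = 2, seed = 47)
  win <- build_reduced_reference(tx)
  trimmed <- lapply(dge$reads, trim_adapter, adapter = adapter)
  res <- count_tags(trimmed, win)
  oracle <- oracle_tag_match(trimmed[["C1"]], win)
  expect_equal(res$stats$mm0[1], sum(oracle$status == "unambiguous" &
                                       oracle$mismatches == 0))
  expect_equal(res$stats$mm1[1], sum(oracle$status == "unambiguous" &
                                       oracle$mismatches == 1))
  expect_equal(res$stats$mm2[1], sum(oracle$status == "unambiguous" &
                                       oracle$mismatches == 2))
  expect_equal(res$stats$ambiguous[1], sum(oracle$status == "ambiguous"))
  expect_equal(res$stats$no_match[1], sum(oracle$status == "no_match"))
  # per-gene totals also agree
  ocnt <- table(oracle$gene_symbol[oracle$status == "unambiguous"])
  pcnt <- tapply(res$counts$C1, res$counts$gene_symbol, sum)
  pcnt <- pcnt[pcnt > 0]
  expect_equal(as.vector(pcnt[names(ocnt)]), as.vector(ocnt))
})

test_that("mapping statistics identities hold on a noisy run", {
  tx <- generate_transcriptome(20, seed = 53)
  truth <- make_truth(tx, n_de = 0, seed = 53)
  nm <- noise_model(seq_error_rate = 0.05, library_sizes = rep(1000L, 4))
  dge <- generate_dge_reads(truth, tx, nm, n_samples = 4, seed = 53)
  win <- build_reduced_reference(tx)
  res <- count_tags(lapply(dge$reads, trim_adapter, adapter = adapter), win)
  expect_equal(res$stats$total,
               res$stats$unambiguous + res$stats$ambiguous +
                 res$stats$no_match)
  expect_equal(res$stats$unambiguous,
               res$stats$mm0 + res$stats$mm1 + res$stats$mm2)
})

make_counts <- function(df) {
  out <- tibble::tibble(window_id = df$window_id,
                        transcript_id = df$window_id,
                        gene_symbol = df$gene_symbol,
                        is_3prime_most = TRUE)
  for (cn in setdiff(names(df), c("window_id", "gene_symbol"))) {
    out[[cn]] <- df[[cn]]
  }
  xplatde:::set_stage(out, "raw")
}

test_that("the low-count filter never removes windows of genes with <= 2 windows", {
  withr::with_seed(59, {
    df <- tibble::tibble(
      window_id = sprintf("w%02d", 1:6),
      gene_symbol = c("A", "B", "B", "C", "C", "C"),
      s1 = rpois(6, 5), s2 = rpois(6, 5), s3 = rpois(6, 5))
  })
  filt <- filter_low_probes(make_counts(df))
  kept <- filt$window_id
  expect_true(all(sprintf("w%02d", 1:3) %in% kept))  # 1- and 2-window genes
  # algebraic check over random pairs: mean - se = min for two values
  for (i in 1:20) {
    x <- rpois(2, 20)
    expect_equal(mean(x) - sd(x) / sqrt(2), min(x))
  }
})

test_that("a consistently weak window is removed by the mean-minus-SE rule", {
  df <- tibble::tibble(
    window_id = c("w1", "w2", "w3"),
    gene_symbol = c("G", "G", "G"),
    s1 = c(10, 10, 0), s2 = c(10, 10, 0), s3 = c(10, 10, 0))
  # mean = 6.667, se = sd/sqrt(3) = 3.333; 0 < 3.333 in all samples
  filt <- filter_low_probes(make_counts(df))
  expect_setequal(filt$window_id, c("w1", "w2"))
})

test_that("normalization equalizes totals to the median and scales cells exactly", {
  df <- tibble::tibble(
    window_id = c("w1", "w2"), gene_symbol = c("A", "B"),
    s1 = c(10, 90), s2 = c(150, 50), s3 = c(100, 200))
  filt <- xplatde:::set_stage(make_counts(df), "filtered")
  norm <- normalize_totals(filt)
  expect_equal(sum(norm$s1), 200)
  expect_equal(sum(norm$s2), 200)
  expect_equal(sum(norm$s3), 200)
  expect_equal(norm$s1[1], 20)  # 10 * (200/100)
  zero <- df; zero$s1 <- 0
  expect_error(normalize_totals(xplatde:::set_stage(make_counts(zero),
                                                    "filtered")),
               "s1")
})

test_that("gene summation conserves per-sample totals", {
  withr::with_seed(61, {
    df <- tibble::tibble(
      window_id = sprintf("w%02d", 1:10),
      gene_symbol = sample(c("A", "B", "C"), 10, TRUE),
      s1 = runif(10, 0, 50), s2 = runif(10, 0, 50))
  })
  norm <- xplatde:::set_stage(make_counts(df), "normalized")
  gs <- sum_by_gene(norm)
  expect_equal(sum(gs$s1), sum(df$s1))
  expect_equal(sum(gs$s2), sum(df$s2))
  expect_equal(gs$s1[gs$gene_symbol == "A"],
               sum(df$s1[df$gene_symbol == "A"]))
})

test_that("DGE log2ratios use the pseudocount and mark double zeros missing", {
  gc <- tibble::tibble(gene_symbol = c("A", "B", "C"),
                       C1 = c(10, 7, 0), E1 = c(20, 7, 0))
  gc <- xplatde:::set_stage(gc, "gene-summed")
  lr <- dge_log2ratio(gc, tibble::tibble(control = "C1", treated = "E1"))
  expect_equal(lr[[2]][1], log2(20.5 / 10.5))
  expect_equal(lr[[2]][2], 0)
  expect_true(is.na(lr[[2]][3]))
  expect_error(
    dge_log2ratio(gc, tibble::tibble(control = "C9", treated = "E1")),
    "unknown sample")
})

test_that("stage transitions are enforced in order", {
  gc <- tibble::tibble(gene_symbol = "A", C1 = 1)
  expect_error(normalize_totals(xplatde:::set_stage(gc, "raw")), "filtered")
  expect_error(sum_by_gene(xplatde:::set_stage(gc, "raw")), "normalized")
  expect_error(dge_log2ratio(xplatde:::set_stage(gc, "raw"),
                             tibble::tibble(control = "C1", treated = "C1")),
               "gene-summed")
})
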