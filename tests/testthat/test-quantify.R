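adapter <- "AGATCGGAAGAGCACACGTCT"

test_that("adapter trimming removes exact and degenerate occurrences", {
  insert <- "ACGTACGTACGTACGTAA" # 18 nt
  r <- trim_adapter(paste0(insert, adapter), adapter)
  expect_equal(r$sequence, insert)
  expect_true(r$kept)

  # short insert is trimmed but flagged for discarding
  r10 <- trim_adapter(paste0("ACGTACGTAC", adapter), adapter)
  expect_equal(nchar(r10$sequence), 10L)
  expect_false(r10$kept)

  # no adapter at all: read untouched
  r0 <- trim_adapter("ACGTACGTACGTACGTACGTACGTAC", adapter)
  expect_equal(r0$sequence, "ACGTACGTACGTACGTACGTACGTAC")
  expect_error(trim_adapter("ACGT", ""), "adapter")
})

test_that("trimming tolerates errors up to the rate and matches a brute scan", {
  insert <- "TTTTCCCCGGGGAAAATTTT"
  # partial 10 nt adapter at the 3' end with 1 mismatch: rate 0.10 <= 0.15
  part <- sub("^(.{5})G", "\\1T", substr(adapter, 1, 10))
  r <- trim_adapter(paste0(insert, part), adapter, max_error_rate = 0.15)
  expect_equal(r$sequence, insert)
  # same occurrence at rate cap 0.05: floor(0.05*10)=0 errors, so the
  # mismatched 10-mer must survive (at most a tiny exact 3'-suffix match of
  # the adapter start may still be clipped)
  r2 <- trim_adapter(paste0(insert, part), adapter, max_error_rate = 0.05)
  expect_gte(nchar(r2$sequence), nchar(insert) + 8L)

  # brute-force oracle: best cut by exhaustive edit-distance over all cut
  # points, on reads with an internal adapter + read-through tail
  set.seed(42)
  for (k in 1:20) {
    ins <- paste(sample(c("A", "C", "G", "T"), 17, TRUE), collapse = "")
    tail_ <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    read <- paste0(ins, adapter, tail_)
    n <- nchar(read)
    feasible <- vapply(0:(n - 1), function(cut) {
      avail <- n - cut
      ml <- min(nchar(adapter), avail)
      ed <- min(utils::adist(substr(adapter, 1, ml),
                             substring(read, cut + 1, cut + seq_len(avail))))
      ed <= floor(0.15 * ml)
    }, logical(1))
    r <- trim_adapter(read, adapter)
    expect_true(feasible[nchar(r$sequence) + 1L])
    expect_equal(r$sequence, ins)
  }
})

test_that("knowledge-based assignment follows maximal arm overlap", {
  ref <- toy_reference()
  # read [1,23): 21 bases in the 5p arm, 0 in the 3p arm
  a <- assign_read(toy_alignment("mirA", 1L, 23L), ref)
  expect_equal(a$mature_name, "mirA-5p")
  expect_equal(a$method, "knowledge")
  # read [30,46): overlaps neither arm
  b <- assign_read(toy_alignment("mirA", 30L, 46L), ref)
  expect_true(is.na(b$mature_name))
  expect_equal(b$unassigned_reason, "no_overlap")
  # equal positive overlap with both arms: ambiguous
  # arms [0,22) and [48,70): read [20,50) overlaps 2 and 2
  c_ <- assign_read(toy_alignment("mirA", 20L, 50L), ref)
  expect_equal(c_$unassigned_reason, "ambiguous")
  expect_error(assign_read(toy_alignment("nope", 0L, 20L), ref), "nope")
})

test_that("position-based assignment splits at the precursor midpoint", {
  ref <- toy_reference() # mirB is unannotated, length 80, midpoint 40
  r3 <- assign_read(toy_alignment("mirB", 50L, 70L), ref)
  expect_equal(r3$mature_name, "mirB-3p")
  expect_equal(r3$method, "position")
  r5 <- assign_read(toy_alignment("mirB", 5L, 25L), ref)
  expect_equal(r5$mature_name, "mirB-5p")
  # read centred exactly on the midpoint is ambiguous
  rm_ <- assign_read(toy_alignment("mirB", 30L, 50L), ref)
  expect_equal(rm_$unassigned_reason, "ambiguous")
})

test_that("per-sample quantification counts and conserves reads", {
  ref <- toy_reference()
  aln <- rbind(
    toy_alignment("mirA", 0L, 20L), toy_alignment("mirA", 2L, 22L),
    toy_alignment("mirA", 1L, 21L),                      # 3 in 5p arm
    toy_alignment("mirA", 48L, 68L), toy_alignment("mirA", 50L, 70L), # 2 in 3p
    toy_alignment("mirA", 30L, 46L),                     # unassigned
    toy_alignment("mirB", 41L, 61L)                      # position 3p
  )
  cnt <- quantify_sample(aln, ref)
  expect_equal(cnt[["mirA-5p"]], 3L)
  expect_equal(cnt[["mirA-3p"]], 2L)
  expect_equal(cnt[["mirB-3p"]], 1L)
  log <- attr(cnt, "assignment_log")
  expect_equal(log$n_assigned + log$n_no_overlap + log$n_ambiguous,
               log$n_input)
  expect_equal(sum(cnt), log$n_assigned)

  empty <- quantify_sample(aln[0, ], ref)
  expect_true(all(empty == 0L))
})

test_that("conservation holds on random alignment fixtures", {
  ref <- simulate_reference(30, 0.5, seed = 5)
  set.seed(6)
  for (k in 1:5) {
    n <- 500
    i <- sample(nrow(ref$precursors), n, TRUE)
    len <- ref$precursors$length[i]
    st <- vapply(len, function(L) sample.int(L - 15L, 1L) - 1L, integer(1))
    en <- pmin(st + 14L + vapply(len - st - 14L, function(m)
      sample.int(max(m, 1L), 1L), integer(1)), len)
    aln <- data.frame(read_id = paste0("r", 1:n),
                      precursor_id = ref$precursors$precursor_id[i],
                      start = st, end = en, is_primary = TRUE)
    cnt <- quantify_sample(aln, ref)
    log <- attr(cnt, "assignment_log")
    expect_equal(sum(cnt) + log$n_no_overlap + log$n_ambiguous, n)
  }
})

test_that("knowledge and position paths agree when arms tile the halves", {
  # annotated arms exactly covering [0, 40) and [40, 80): any read not
  # crossing the midpoint must be assigned identically by both methods
  mkref <- function(annotated) {
    arms <- if (annotated) {
      data.frame(precursor_id = "m", arm5p_start = 0L, arm5p_end = 40L,
                 arm3p_start = 40L, arm3p_end = 80L)
    } else {
      data.frame(precursor_id = "m", arm5p_start = NA_integer_,
                 arm5p_end = NA_integer_, arm3p_start = NA_integer_,
                 arm3p_end = NA_integer_)
    }
    structure(list(
      precursors = data.frame(precursor_id = "m",
                              sequence = paste(rep("A", 80), collapse = ""),
                              chromosome = "chr1", length = 80L),
      arms = arms), class = "mirna_reference")
  }
  refk <- mkref(TRUE); refp <- mkref(FALSE)
  set.seed(8)
  for (k in 1:200) {
    st <- sample(0:60, 1)
    en <- st + sample(15:20, 1)
    if (st < 40 && en > 40) next # crosses the midpoint: exempt by design
    ak <- assign_read(toy_alignment("m", st, en), refk)
    ap <- assign_read(toy_alignment("m", st, en), refp)
    expect_equal(ak$mature_name, ap$mature_name)
  }
})

test_that("count matrices span the full mature name space", {
  ref <- toy_reference()
  c1 <- stats::setNames(c(3L, 0L, 0L, 0L), mature_names(ref))
  c2 <- stats::setNames(c(0L, 2L, 1L, 0L), mature_names(ref))
  m <- build_count_matrix(list(s1 = c1, s2 = c2), ref)
  expect_equal(dim(m), c(4L, 2L)) # 2 precursors -> 4 rows always
  expect_equal(m["mirA-5p", "s2"], 0L)
  expect_equal(colSums(m), c(s1 = 3L, s2 = 3L))
  expect_error(build_count_matrix(list(s1 = c1, s1 = c2), ref), "duplicate")

  big <- simulate_reference(40, 0.3, seed = 2)
  mm <- build_count_matrix(list(only = stats::setNames(
    integer(80), mature_names(big))), big)
  expect_equal(nrow(mm), 2L * nrow(big$precursors))
})
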