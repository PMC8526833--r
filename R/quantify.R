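#' Trim a 3' adapter from a read by exhaustive edit-distance scan
#'
#' Finds the best semi-global occurrence of the adapter (or of an adapter
#' prefix reaching the 3' end of the read) allowing mismatches, insertions
#' and deletions, and removes it together with everything 3' of it. A
#' candidate occurrence at cut point `c` is accepted when its edit distance
#' is at most `floor(max_error_rate * matched_adapter_length)`; among
#' accepted candidates the one with the most matching adapter bases
#' (matched length minus errors) wins, ties going to fewer errors and then
#' to the leftmost cut, so a long slightly-degenerate occurrence beats a
#' short spurious suffix match. Reads whose trimmed insert is shorter than
#' `min_length` are flagged for discarding.
#'
#' The scan is exhaustive over cut points and match lengths —
#' O(read x adapter x read) — favouring fidelity over speed at the scale of
#' 50 nt small-RNA reads.
#'
#' @param read_seq read sequence (character scalar)
#' @param adapter_seq 3' adapter sequence; must be non-empty
#' @param max_error_rate maximum errors per matched adapter base (default
#'   0.15, counting mismatches, insertions and deletions alike)
#' @param min_length minimum insert length kept (default 14 nt)
#' @return list with `sequence` (the trimmed insert) and `kept`
#'   (`sequence` has at least `min_length` bases)
#' @export
trim_adapter <- function(read_seq, adapter_seq, max_error_rate = 0.15,
                         min_length = 14L) {
  if (!nzchar(adapter_seq)) stop("adapter must be non-empty")
  stopifnot(max_error_rate >= 0, max_error_rate < 1, min_length >= 1)
  n <- nchar(read_seq)
  m <- nchar(adapter_seq)
  best <- NULL # (cut, ed, matched_len)
  for (cut in 0:(n - 1L)) {
    avail <- n - cut
    matched_len <- min(m, avail)
    max_ed <- floor(max_error_rate * matched_len)
    adapter_part <- substr(adapter_seq, 1L, matched_len)
    # adapter may be followed by read-through bases, which are removed
    # anyway: align against every read window starting at cut+1
    lo <- max(1L, matched_len - max_ed)
    hi <- min(avail, matched_len + max_ed)
    windows <- substring(read_seq, cut + 1L, cut + (lo:hi))
    ed <- min(utils::adist(adapter_part, windows))
    if (ed <= max_ed) {
      score <- matched_len - ed
      if (is.null(best) || score > best$score ||
          (score == best$score && ed < best$ed)) {
        best <- list(cut = cut, score = score, ed = ed)
      }
    }
  }
  insert <- if (is.null(best)) read_seq else substr(read_seq, 1L, best$cut)
  list(sequence = insert, kept = nchar(insert) >= min_length)
}

#' Assign one precursor alignment to a mature miRNA arm
#'
#' Precursors with annotated arms use the knowledge-based rule: the read is
#' assigned to the arm with the larger base-pair overlap; zero overlap with
#' both arms is `no_overlap`, an exact positive tie is `ambiguous`.
#' Unannotated precursors use the position-based rule: the read midpoint is
#' compared with the precursor midpoint; strictly left means `-5p`, strictly
#' right means `-3p`, exactly on it is `ambiguous`.
#'
#' @param alignment one-row data.frame (or list) with `precursor_id`,
#'   `start`, `end` in 0-based half-open precursor coordinates
#' @param ref a `mirna_reference`
#' @return list with `mature_name` (or `NA`), `method`
#'   (`"knowledge"`/`"position"`), `unassigned_reason` (`NA`,
#'   `"no_overlap"` or `"ambiguous"`)
#' @export
assign_read <- function(alignment, ref) {
  res <- assign_reads(data.frame(precursor_id = alignment$precursor_id,
                                 start = alignment$start,
                                 end = alignment$end), ref)
  list(mature_name = res$mature_name[1],
       method = res$method[1],
       unassigned_reason = res$unassigned_reason[1])
}

#' Vectorized arm assignment for a table of alignments
#'
#' @param alignments data.frame with `precursor_id`, `start`, `end`
#' @param ref a `mirna_reference`
#' @return data.frame with `mature_name`, `method`, `unassigned_reason`
#' @export
assign_reads <- function(alignments, ref) {
  i <- match(alignments$precursor_id, ref$precursors$precursor_id)
  if (anyNA(i)) {
    stop("unknown precursor: ", alignments$precursor_id[is.na(i)][1])
  }
  len <- ref$precursors$length[i]
  a5s <- ref$arms$arm5p_start[i]; a5e <- ref$arms$arm5p_end[i]
  a3s <- ref$arms$arm3p_start[i]; a3e <- ref$arms$arm3p_end[i]
  annotated <- !is.na(a5s) & !is.na(a3s)
  s <- alignments$start; e <- alignments$end
  mature <- rep(NA_character_, length(i))
  reason <- rep(NA_character_, length(i))
  method <- ifelse(annotated, "knowledge", "position")

  # knowledge-based: maximal base-pair overlap with the annotated arms
  ov5 <- pmax(0L, pmin(e, a5e) - pmax(s, a5s))
  ov3 <- pmax(0L, pmin(e, a3e) - pmax(s, a3s))
  k <- which(annotated)
  both_zero <- ov5[k] == 0L & ov3[k] == 0L
  tie <- ov5[k] == ov3[k] & ov5[k] > 0L
  win5 <- ov5[k] > ov3[k]
  mature[k[win5]] <- paste0(alignments$precursor_id[k[win5]], "-5p")
  win3 <- !win5 & !both_zero & !tie
  mature[k[win3]] <- paste0(alignments$precursor_id[k[win3]], "-3p")
  reason[k[both_zero]] <- "no_overlap"
  reason[k[tie]] <- "ambiguous"

  # position-based: read midpoint vs precursor midpoint
  p <- which(!annotated)
  mid <- (s[p] + e[p]) / 2
  pmid <- len[p] / 2
  mature[p[mid < pmid]] <- paste0(alignments$precursor_id[p[mid < pmid]], "-5p")
  mature[p[mid > pmid]] <- paste0(alignments$precursor_id[p[mid > pmid]], "-3p")
  reason[p[mid == pmid]] <- "ambiguous"

  data.frame(mature_name = mature, method = method,
             unassigned_reason = reason, stringsAsFactors = FALSE)
}

#' Quantify mature miRNAs for one sample
#'
#' Counts primary alignments per mature name over the full mature-name space
#' of the reference. Unassigned reads (no arm overlap, or ambiguous
#' placement) are not counted but are tallied in the attached log so that
#' assigned + unassigned always equals the number of input alignments.
#'
#' @param alignments data.frame as returned by [read_alignments()]
#' @param ref a `mirna_reference`
#' @return named integer vector over [mature_names()] with attribute
#'   `assignment_log` (list: `n_input`, `n_assigned`, `n_no_overlap`,
#'   `n_ambiguous`, `n_knowledge`, `n_position`)
#' @export
quantify_sample <- function(alignments, ref) {
  nm <- mature_names(ref)
  counts <- stats::setNames(integer(length(nm)), nm)
  log <- list(n_input = nrow(alignments), n_assigned = 0L,
              n_no_overlap = 0L, n_ambiguous = 0L,
              n_knowledge = 0L, n_position = 0L)
  if (nrow(alignments)) {
    asg <- assign_reads(alignments, ref)
    assigned <- !is.na(asg$mature_name)
    tab <- table(asg$mature_name[assigned])
    counts[names(tab)] <- as.integer(tab)
    log$n_assigned <- sum(assigned)
    log$n_no_overlap <- sum(asg$unassigned_reason == "no_overlap", na.rm = TRUE)
    log$n_ambiguous <- sum(asg$unassigned_reason == "ambiguous", na.rm = TRUE)
    log$n_knowledge <- sum(assigned & asg$method == "knowledge")
    log$n_position <- sum(assigned & asg$method == "position")
  }
  attr(counts, "assignment_log") <- log
  counts
}

#' Merge per-sample count vectors into a mature count matrix
#'
#' The matrix always spans the full mature-name space (two rows per
#' precursor), so undetected mature miRNAs appear as zero rows and matrices
#' from different sample batches are directly comparable.
#'
#' @param per_sample_counts named list of vectors from [quantify_sample()];
#'   names are sample ids
#' @param ref a `mirna_reference`
#' @return integer matrix, rows = mature names, columns = samples
#' @export
build_count_matrix <- function(per_sample_counts, ref) {
  ids <- names(per_sample_counts)
  if (is.null(ids) || any(!nzchar(ids))) stop("samples must be named")
  if (anyDuplicated(ids)) stop("duplicate sample id: ",
                               ids[duplicated(ids)][1])
  nm <- mature_names(ref)
  m <- matrix(0L, nrow = length(nm), ncol = length(ids),
              dimnames = list(nm, ids))
  for (j in seq_along(ids)) {
    v <- per_sample_counts[[j]]
    m[names(v), j] <- as.integer(v)
  }
  m
}
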