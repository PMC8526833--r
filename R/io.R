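#' Read a precursor miRNA reference with optional arm annotation
#'
#' Loads precursor sequences from FASTA together with an arm-annotation table
#' giving, for a subset of precursors, the intervals of the mature 5p and 3p
#' arms. Precursors with annotated arms are later quantified by the
#' knowledge-based method; the rest fall back to the position-based midpoint
#' split. All intervals are 0-based half-open in precursor coordinates.
#'
#' @param fasta_path path to a precursor FASTA file. Header word one is the
#'   precursor id.
#' @param arm_table_path path to a tab-separated arm table with columns
#'   `precursor_id`, `arm` (`5p`/`3p`), `start`, `end`, `chromosome`, or
#'   `NULL` for a reference without any arm annotation.
#' @return an object of class `mirna_reference`: a list with
#'   `precursors` (data.frame: `precursor_id`, `sequence`, `chromosome`,
#'   `length`) and `arms` (data.frame: `precursor_id`, `arm5p_start`,
#'   `arm5p_end`, `arm3p_start`, `arm3p_end`; `NA` where unannotated).
#' @export
read_reference <- function(fasta_path, arm_table_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("malformed FASTA header: empty precursor id")
  }
  prec <- data.frame(
    precursor_id = ids,
    sequence = as.character(seqs),
    chromosome = NA_character_,
    length = Biostrings::width(seqs),
    stringsAsFactors = FALSE
  )
  arms <- data.frame(
    precursor_id = ids,
    arm5p_start = NA_integer_, arm5p_end = NA_integer_,
    arm3p_start = NA_integer_, arm3p_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (!is.null(arm_table_path)) {
    tab <- utils::read.delim(arm_table_path, stringsAsFactors = FALSE)
    needed <- c("precursor_id", "arm", "start", "end", "chromosome")
    if (!all(needed %in% names(tab))) {
      stop("arm table must have columns: ", paste(needed, collapse = ", "))
    }
    for (k in seq_len(nrow(tab))) {
      row <- tab[k, ]
      i <- match(row$precursor_id, prec$precursor_id)
      if (is.na(i)) stop("arm table names unknown precursor: ", row$precursor_id)
      if (row$start < 0 || row$end > prec$length[i] || row$start >= row$end) {
        stop("arm interval out of bounds for precursor ", row$precursor_id)
      }
      if (identical(row$arm, "5p")) {
        arms$arm5p_start[i] <- as.integer(row$start)
        arms$arm5p_end[i] <- as.integer(row$end)
      } else if (identical(row$arm, "3p")) {
        arms$arm3p_start[i] <- as.integer(row$start)
        arms$arm3p_end[i] <- as.integer(row$end)
      } else {
        stop("arm must be '5p' or '3p', got: ", row$arm)
      }
      prec$chromosome[i] <- as.character(row$chromosome)
    }
  }
  ref <- structure(list(precursors = prec, arms = arms),
                   class = "mirna_reference")
  validate_reference(ref)
  ref
}

#' Validate a `mirna_reference`
#'
#' Checks precursor id uniqueness, sequence alphabet, arm-interval bounds and
#' the 5p-before-3p ordering. Called by every constructor; exported so
#' hand-built references can be checked too.
#'
#' @param ref a `mirna_reference`
#' @return `ref`, invisibly, or an error naming the offending precursor.
#' @export
validate_reference <- function(ref) {
  prec <- ref$precursors
  arms <- ref$arms
  if (anyDuplicated(prec$precursor_id)) {
    stop("duplicate precursor ids: ",
         paste(unique(prec$precursor_id[duplicated(prec$precursor_id)]),
               collapse = ", "))
  }
  bad <- grepl("[^ACGTUNacgtun]", prec$sequence)
  if (any(bad)) stop("invalid sequence alphabet in: ", prec$precursor_id[bad][1])
  for (i in seq_len(nrow(prec))) {
    len <- prec$length[i]
    a <- arms[i, ]
    for (side in c("5p", "3p")) {
      s <- a[[paste0("arm", side, "_start")]]
      e <- a[[paste0("arm", side, "_end")]]
      if (is.na(s) != is.na(e)) {
        stop("half-specified ", side, " arm for ", prec$precursor_id[i])
      }
      if (!is.na(s) && (s < 0 || e > len || s >= e)) {
        stop("arm interval out of bounds for precursor ", prec$precursor_id[i])
      }
    }
    if (!is.na(a$arm5p_end) && !is.na(a$arm3p_start) &&
        a$arm5p_end > a$arm3p_start) {
      stop("5p arm overlaps 3p arm in precursor ", prec$precursor_id[i])
    }
  }
  invisible(ref)
}

#' Mature miRNA name space of a reference
#'
#' Every precursor contributes exactly two mature names, `<id>-5p` and
#' `<id>-3p`, whether or not its arms are annotated, so a reference of `n`
#' precursors defines a `2n`-row count-matrix name space.
#'
#' @param ref a `mirna_reference`
#' @return character vector of length `2 * nrow(ref$precursors)`
#' @export
mature_names <- function(ref) {
  as.vector(rbind(paste0(ref$precursors$precursor_id, "-5p"),
                  paste0(ref$precursors$precursor_id, "-3p")))
}

#' Whether each precursor carries arm annotation
#' @param ref a `mirna_reference`
#' @return named logical vector over precursor ids
#' @export
is_annotated <- function(ref) {
  ann <- !is.na(ref$arms$arm5p_start) & !is.na(ref$arms$arm3p_start)
  names(ann) <- ref$precursors$precursor_id
  ann
}

#' Write a reference back to FASTA + arm table
#' @param ref a `mirna_reference`
#' @param fasta_path,arm_table_path output paths
#' @return invisibly, the two paths
#' @export
write_reference <- function(ref, fasta_path, arm_table_path) {
  seqs <- Biostrings::DNAStringSet(ref$precursors$sequence)
  names(seqs) <- ref$precursors$precursor_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- is_annotated(ref)
  rows <- list()
  for (i in which(ann)) {
    a <- ref$arms[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      precursor_id = rep(a$precursor_id, 2L),
      arm = c("5p", "3p"),
      start = c(a$arm5p_start, a$arm3p_start),
      end = c(a$arm5p_end, a$arm3p_end),
      chromosome = rep(ref$precursors$chromosome[i], 2L))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(precursor_id = character(), arm = character(),
               start = integer(), end = integer(), chromosome = character())
  utils::write.table(tab, arm_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, arm_table_path))
}

#' Read primary mapped alignments against precursors from a SAM file
#'
#' Consumes only FLAG, RNAME, POS and CIGAR. SAM's 1-based POS is converted
#' once at this boundary to the package-wide 0-based half-open convention;
#' `end` is `start` plus the reference span implied by the CIGAR. Secondary
#' and supplementary alignments and unmapped records are excluded; the counts
#' of skipped records are attached as attributes.
#'
#' @param sam_path path to a SAM file whose `@SQ` names are precursor ids
#' @param ref a `mirna_reference`; alignments to unknown precursors error
#' @return data.frame (`read_id`, `precursor_id`, `start`, `end`,
#'   `is_primary`) with attributes `n_unmapped` and `n_secondary`.
#' @export
read_alignments <- function(sam_path, ref) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  flags_all <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = "flag"))[[1]]$flag
  n_unmapped <- sum(bitwAnd(flags_all, 4L) != 0L)
  n_secondary <- sum(bitwAnd(flags_all, 4L) == 0L &
                       (bitwAnd(flags_all, 256L) != 0L |
                          bitwAnd(flags_all, 2048L) != 0L))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = "qname")
  aln <- as.data.frame(GenomicAlignments::readGAlignments(bam, param = param))
  prec_id <- as.character(aln$seqnames)
  unknown <- setdiff(unique(prec_id), ref$precursors$precursor_id)
  if (length(unknown)) {
    stop("alignments reference precursors absent from the reference: ",
         paste(unknown, collapse = ", "))
  }
  out <- data.frame(
    read_id = aln$qname,
    precursor_id = prec_id,
    start = aln$start - 1L,
    end = aln$end,
    is_primary = rep(TRUE, nrow(aln)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_secondary") <- n_secondary
  out
}

#' Write alignment records as SAM
#'
#' Emits a minimal SAM file (`@SQ` headers from the reference; FLAG, RNAME,
#' POS, CIGAR populated; sequence/quality starred) understood by
#' [read_alignments()] and by samtools.
#'
#' @param alignments data.frame with `read_id`, `precursor_id`, `start`,
#'   `end` (0-based half-open)
#' @param ref a `mirna_reference`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_sam <- function(alignments, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ref$precursors$precursor_id,
                     ref$precursors$length), con)
  if (nrow(alignments)) {
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       alignments$read_id, alignments$precursor_id,
                       alignments$start + 1L,
                       alignments$end - alignments$start), con)
  }
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Descriptions are preserved as an attribute.
#'
#' @param path GMT file path
#' @param library_label one of `"GO"`, `"KEGG"`, `"REACTOME"`, `"custom"`
#' @return named list of character vectors (class `gene_set_library`) with
#'   attributes `descriptions` and `library_label`
#' @export
read_gmt <- function(path, library_label = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name in GMT: ",
         names_[duplicated(names_)][1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("GMT set with no genes: ", names_[empty][1])
  names(sets) <- names_
  structure(sets,
            descriptions = stats::setNames(
              vapply(fields, `[`, character(1), 2L), names_),
            library_label = library_label,
            class = "gene_set_library")
}

#' Write a GMT gene-set library
#' @param sets named list of character vectors; optional `descriptions` attr
#' @param path output path
#' @return invisibly, `path`
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a miRNA-to-target-gene map
#'
#' Tab-separated, two columns `mirna` and `gene`. Duplicate pairs are
#' removed with a warning (set semantics).
#'
#' @param path TSV path
#' @return data.frame with columns `mirna`, `gene`, no duplicate rows
#' @export
read_target_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(tab))) {
    stop("target map must have columns 'mirna' and 'gene'")
  }
  dup <- duplicated(tab[c("mirna", "gene")])
  if (any(dup)) {
    warning(sum(dup), " duplicate miRNA-target pairs removed")
    tab <- tab[!dup, , drop = FALSE]
  }
  ok <- grepl("(-5p|-3p)$", tab$mirna) | grepl("^[A-Za-z0-9._-]+$", tab$mirna)
  if (!all(ok)) stop("syntactically invalid miRNA name: ", tab$mirna[!ok][1])
  rownames(tab) <- NULL
  tab
}

#' Write / read an integer count matrix as TSV
#'
#' Rows are mature miRNAs, columns samples; the first column (`mirna`) holds
#' row names. Round-trips losslessly; non-integer cells on read are an error.
#'
#' @param counts integer matrix with row and column names
#' @param path TSV path
#' @return `write_count_matrix`: invisibly `path`;
#'   `read_count_matrix`: integer matrix.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(mirna = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(m != round(m), na.rm = TRUE) || anyNA(m)) {
    stop("non-integer count cell in ", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Read / write a subject questionnaire table
#'
#' CSV with one row per subject; raw covariates as collected (age, sex,
#' height/weight, smoking, alcohol and coffee grams/day, MET-hour components,
#' occupational class, menopausal status). Categorization is done separately
#' by [categorize_cohort()].
#'
#' @param path CSV path
#' @return data.frame
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(tab)) stop("cohort table needs 'subject_id'")
  if (anyDuplicated(tab$subject_id)) stop("duplicate subject_id")
  tab
}

#' @rdname read_cohort
#' @param cohort data.frame to write
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
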