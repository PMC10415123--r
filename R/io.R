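# Readers and writers: tcount TSV, FASTA, minimal SAM, count-matrix TSV,
# GMT gene sets and key=value configuration files. TSV dialect throughout:
# tab-separated, header row, '.' decimal, no quoting, NA as empty field.

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Read a tcount table
#'
#' Accepts SLAM-DUNK-style TSV files. Requires a gene identifier column
#' (`gene_id` or `gene_name`) plus `ReadCount` and `TcReadCount`; any extra
#' columns are preserved verbatim.
#'
#' @param path TSV file path
#' @return tcount data.frame (identifier column normalized to `gene_id`)
#' @export
read_tcount <- function(path) {
  tab <- read_tsv_plain(path)
  if ("gene_name" %in% names(tab) && !"gene_id" %in% names(tab)) {
    names(tab)[names(tab) == "gene_name"] <- "gene_id"
  }
  for (col in c("gene_id", "ReadCount", "TcReadCount")) {
    if (!col %in% names(tab)) {
      stop(sprintf("tcount file '%s' is missing required column '%s'",
                   path, col), call. = FALSE)
    }
  }
  bad <- which(tab$TcReadCount > tab$ReadCount)
  if (length(bad) > 0) {
    stop(sprintf("TcReadCount > ReadCount at row %d of '%s'", bad[1], path),
         call. = FALSE)
  }
  tab
}

#' Write a tcount table
#'
#' @param table tcount data.frame
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_tcount <- function(table, path) {
  stopifnot(all(c("gene_id", "ReadCount", "TcReadCount") %in% names(table)))
  write_tsv_plain(table, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased on read.
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty FASTA file", call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("malformed FASTA: line 1 is not a header", call. = FALSE)
  idx <- cumsum(hdr)
  names_out <- sub("^>\\s*", "", lines[hdr])
  names_out <- sub("\\s.*$", "", names_out)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1),
                 collapse = "")
  out <- stats::setNames(toupper(unname(seqs)), names_out)
  if (anyDuplicated(names_out)) stop("duplicate FASTA record names", call. = FALSE)
  out
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# MD tag for a read against its reference segment (matches/mismatch encoding;
# no indels in this minimal subset).
md_tag <- function(read_seq, ref_seg) {
  rv <- strsplit(ref_seg, "")[[1]]
  sv <- strsplit(read_seq, "")[[1]]
  mism <- which(rv != sv)
  out <- character(0)
  prev <- 0L
  for (i in mism) {
    out <- c(out, as.character(i - prev - 1L), rv[i])
    prev <- i
  }
  out <- c(out, as.character(length(rv) - prev))
  paste(out, collapse = "")
}

#' Write an aligned read set as minimal SAM
#'
#' Header carries reference names and lengths; records are sense-strand
#' (FLAG 0), all-match CIGAR, 1-based POS, with an MD tag encoding
#' mismatches against the reference. Simulation origin labels, when present,
#' are written as an `XO:Z:` tag.
#'
#' @param reads `aligned_reads`
#' @param path output SAM path
#' @return `path`, invisibly
#' @export
write_sam_minimal <- function(reads, path) {
  stopifnot(inherits(reads, "aligned_reads"))
  refs <- attr(reads, "reference")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)), con)
  if (nrow(reads) > 0) {
    ref_seg <- substr(refs[reads$gene_id], reads$start + 1L,
                      reads$start + nchar(reads$seq))
    md <- vapply(seq_len(nrow(reads)),
                 function(i) md_tag(reads$seq[i], ref_seg[i]), character(1))
    rec <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tMD:Z:%s",
                   reads$read_id, reads$gene_id, reads$start + 1L,
                   nchar(reads$seq), reads$seq, reads$qual, md)
    if (!is.null(reads$origin)) {
      rec <- paste0(rec, sprintf("\tXO:Z:%s", reads$origin))
    }
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read a minimal SAM file
#'
#' Parses the plain-text subset written by [write_sam_minimal()]: FLAG 0,
#' all-match CIGAR records. POS is converted to the internal 0-based start.
#' Reference sequences must be supplied (FASTA) for downstream conversion
#' counting; `@SQ` lengths are validated against them.
#'
#' @param path SAM file
#' @param reference named character vector of reference sequences
#' @return `aligned_reads`
#' @export
read_sam_minimal <- function(path, reference) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ", lines)]
  sq_names <- sub(".*SN:([^\t]+).*", "\\1", sq)
  sq_len <- as.integer(sub(".*LN:([0-9]+).*", "\\1", sq))
  miss <- setdiff(sq_names, names(reference))
  if (length(miss) > 0) {
    stop("reference missing sequences: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(reference[sq_names]) != sq_len)) {
    stop("@SQ lengths disagree with the reference FASTA", call. = FALSE)
  }
  body <- lines[!hdr]
  if (length(body) == 0L) {
    return(aligned_reads(data.frame(read_id = character(0),
                                    gene_id = character(0),
                                    start = integer(0), seq = character(0),
                                    qual = character(0)), reference))
  }
  fields <- strsplit(body, "\t")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 11L)) {
    stop("malformed SAM record at line ", which(!hdr)[which(nf < 11L)[1]],
         call. = FALSE)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2))
  if (any(flag != 0L)) stop("only FLAG 0 records are supported", call. = FALSE)
  cigar <- get(6)
  seqs <- toupper(get(10))
  if (any(cigar != paste0(nchar(seqs), "M"))) {
    stop("only all-match CIGAR records are supported", call. = FALSE)
  }
  reads <- data.frame(
    read_id = get(1), gene_id = get(3),
    start = as.integer(get(4)) - 1L, seq = seqs, qual = get(11),
    stringsAsFactors = FALSE
  )
  origin <- vapply(fields, function(f) {
    tag <- grep("^XO:Z:", f, value = TRUE)
    if (length(tag) > 0) sub("^XO:Z:", "", tag[1]) else NA_character_
  }, character(1))
  if (!all(is.na(origin))) reads$origin <- origin
  aligned_reads(reads, reference)
}

#' Write a genes x samples count matrix as TSV
#'
#' @param mat numeric matrix with gene rownames and sample colnames
#' @param path output path
#' @return `path`, invisibly
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  invisible(path)
}

#' Read a genes x samples count matrix from TSV
#'
#' @param path TSV with a `gene_id` first column
#' @return numeric matrix with gene rownames
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_plain(path)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id", call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  mat
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated members.
#' Duplicate members within a set are removed (with a message).
#'
#' @param path GMT file
#' @return named list of character vectors; descriptions in attribute
#'   `descriptions`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 3L) {
      stop("malformed GMT line ", i, ": need name, description, members",
           call. = FALSE)
    }
    members <- f[-(1:2)]
    ndup <- sum(duplicated(members))
    if (ndup > 0) {
      message(sprintf("GMT set '%s': removed %d duplicate members", f[1], ndup))
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    descs[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors
#' @param path output path
#' @param descriptions optional named descriptions (default "na")
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults. Sizes are
#' desk scale: the defaults run end to end in well under a minute.
#'
#' @return named list of class `pipeline_config`
#' @export
default_pipeline_config <- function() {
  structure(list(
    n_genes = 400L,
    utr_length_min = 200L, utr_length_max = 1200L,
    u_content_min = 0.15, u_content_max = 0.35,
    orf_length_min = 300L, orf_length_max = 6000L,
    read_length = 100L,
    mode_fraction_null = 0.6, mode_fraction_forwarded = 0.1,
    mode_fraction_exclusive = 0.1, mode_fraction_intensified = 0.1,
    mode_fraction_buffered = 0.1,
    effect_size_log2 = 2,
    n_replicates = 3L, labeling_time = 3, library_size = 2e5,
    dispersion = 0.05, p_conv = 0.024, p_err = 0.001,
    kinetics = "step", loading_lag = 1,
    trim5 = 12L, max_polya_keep = 4L,
    min_base_quality = 27L, min_tc = 1L,
    alpha = 0.05, lfc_threshold = 1.5, deltate_lfc_threshold = 0,
    top_k = 3L, sensitivity_formulation = "excess", min_support = 20L,
    gmt = "", seed = 1L
  ), class = "pipeline_config")
}

#' Read a key=value configuration file
#'
#' Unknown keys are rejected; values are coerced to the type of the default.
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path config file path
#' @param defaults base configuration to override
#' @return `pipeline_config`
#' @export
read_config <- function(path, defaults = default_pipeline_config()) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- defaults
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected key=value): ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(cfg)) {
      stop("unknown configuration key: ", key, call. = FALSE)
    }
    cfg[[key]] <- if (is.numeric(cfg[[key]])) {
      if (is.integer(cfg[[key]])) as.integer(val) else as.numeric(val)
    } else val
  }
  cfg
}

#' Write a configuration as key=value text
#'
#' @param config `pipeline_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, format, character(1), scientific = FALSE)),
             path)
  invisible(path)
}
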