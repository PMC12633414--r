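# Readers and writers for the formats the pipeline touches, plus basic
# assembly statistics.  Coordinates are 0-based half-open everywhere inside
# the package (BED convention); VCF positions are converted at the boundary.

# ---- prob_alignment container -------------------------------------------

#' Construct a probabilistic alignment
#'
#' A `prob_alignment` holds a column-indexed alignment whose rows are either
#' extant sequences (bases and gaps) or reconstructed internal nodes
#' (per-column posterior base-probability vectors with a presence flag).
#' The first row is the reference; a coordinate map links reference base
#' offsets (0-based) to alignment columns.
#'
#' @param rows Named list.  Each element is either a character vector of
#'   single-character tokens (`A/C/G/T/-/N`) for an extant row, or a list
#'   with elements `present` (logical) and `probs` (numeric matrix with 4
#'   columns, rows ignored where absent) for a reconstructed node.
#' @param reference Name of the reference row; defaults to the first.
#' @return An object of class `prob_alignment`.
#' @export
prob_alignment <- function(rows, reference = names(rows)[1]) {
  if (length(rows) == 0L || is.null(names(rows)) || any(names(rows) == "")) {
    abort("`rows` must be a non-empty named list.")
  }
  widths <- vapply(rows, function(r) {
    if (is.character(r)) length(r) else length(r$present)
  }, integer(1))
  if (length(unique(widths)) != 1L) {
    abort("All alignment rows must have the same number of columns.")
  }
  if (!reference %in% names(rows)) abort("`reference` must name a row.")
  ref <- rows[[reference]]
  if (!is.character(ref)) {
    abort("The reference row must be a concrete base sequence, not posterior vectors.")
  }
  for (nm in names(rows)) {
    r <- rows[[nm]]
    if (!is.character(r)) {
      if (!is.matrix(r$probs) || ncol(r$probs) != 4L) {
        abort(sprintf("Row '%s': `probs` must be a 4-column matrix.", nm))
      }
      bad <- r$present & !is.finite(rowSums(r$probs))
      if (any(bad)) abort(sprintf("Row '%s': non-finite posterior at a present column.", nm))
    }
  }
  structure(
    list(
      reference = reference,
      ncol = widths[[1]],
      rows = rows,
      ref_coord_map = which(ref != "-")  # 1-based column index per ref base
    ),
    class = "prob_alignment"
  )
}

#' @export
print.prob_alignment <- function(x, ...) {
  cat(sprintf(
    "<prob_alignment> %d rows x %d columns (reference: %s, %d reference bases)\n",
    length(x$rows), x$ncol, x$reference, length(x$ref_coord_map)
  ))
  invisible(x)
}

#' Extract a node track from an alignment
#'
#' Returns the per-column presence flags and base-probability vectors of one
#' row, converting concrete bases to indicator (one-hot) vectors.
#'
#' @param aln A [prob_alignment].
#' @param name Row name.
#' @return A list with `present` (logical) and `probs` (ncol x 4 matrix).
#' @export
node_track <- function(aln, name) {
  if (!inherits(aln, "prob_alignment")) abort("`aln` must be a prob_alignment.")
  if (!name %in% names(aln$rows)) abort(sprintf("No row named '%s'.", name))
  r <- aln$rows[[name]]
  if (is.character(r)) {
    code <- encode_bases(r)
    probs <- matrix(0, length(code), 4L, dimnames = list(NULL, BASES))
    ok <- code > 0L
    probs[cbind(which(ok), code[ok])] <- 1
    list(present = ok, probs = probs)
  } else {
    probs <- r$probs
    colnames(probs) <- BASES
    list(present = r$present, probs = probs)
  }
}

# ---- pFASTA --------------------------------------------------------------

format_pfasta_row <- function(row) {
  if (is.character(row)) return(row)
  tok <- rep("-", length(row$present))
  idx <- which(row$present)
  if (length(idx)) {
    p <- row$probs[idx, , drop = FALSE]
    tok[idx] <- sprintf("%.6f,%.6f,%.6f,%.6f", p[, 1], p[, 2], p[, 3], p[, 4])
  }
  tok
}

#' Write a probabilistic alignment to pFASTA
#'
#' pFASTA is a plain-text dialect of FASTA for alignments that mix concrete
#' bases with posterior base-probability vectors: FASTA-style header lines,
#' and a body of whitespace-separated per-column tokens, each one of `-`
#' (gap/absent), a single base letter, or `pA,pC,pG,pT` as 6-decimal
#' fixed-point floats.
#'
#' @param aln A [prob_alignment].
#' @param path Output file path.
#' @param tokens_per_line Tokens written per body line.
#' @return `path`, invisibly.
#' @export
write_pfasta <- function(aln, path, tokens_per_line = 20L) {
  if (!inherits(aln, "prob_alignment")) abort("`aln` must be a prob_alignment.")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(aln$rows)) {
    writeLines(paste0(">", nm), con)
    tok <- format_pfasta_row(aln$rows[[nm]])
    idx <- seq_along(tok)
    grp <- ceiling(idx / tokens_per_line)
    writeLines(vapply(split(tok, grp), paste, character(1), collapse = " "), con)
  }
  invisible(path)
}

parse_pfasta_tokens <- function(tokens, name) {
  has_comma <- grepl(",", tokens, fixed = TRUE)
  if (!any(has_comma)) {
    bad <- !tokens %in% c(BASES, tolower(BASES), "-", "N", "n")
    if (any(bad)) {
      abort(sprintf("Row '%s': unparseable token '%s'.", name, tokens[which(bad)[1]]))
    }
    return(toupper(tokens))
  }
  if (any(!has_comma & tokens != "-")) {
    bad <- tokens[which(!has_comma & tokens != "-")[1]]
    abort(sprintf("Row '%s': token '%s' mixes bases into a posterior row.", name, bad))
  }
  probs <- matrix(NA_real_, length(tokens), 4L, dimnames = list(NULL, BASES))
  if (any(has_comma)) {
    parts <- strsplit(tokens[has_comma], ",", fixed = TRUE)
    if (any(lengths(parts) != 4L)) {
      abort(sprintf("Row '%s': posterior token without 4 fields.", name))
    }
    vals <- suppressWarnings(as.numeric(unlist(parts)))
    if (anyNA(vals)) abort(sprintf("Row '%s': non-numeric posterior token.", name))
    probs[has_comma, ] <- matrix(vals, ncol = 4L, byrow = TRUE)
  }
  list(present = has_comma, probs = probs)
}

#' Read an alignment from multi-FASTA or pFASTA
#'
#' @param path Input file.
#' @param format `"pfasta"` (see [write_pfasta()] for the dialect) or
#'   `"fasta"` (plain aligned multi-FASTA).
#' @return A [prob_alignment]; the first record is the reference.
#' @export
read_alignment <- function(path, format = c("pfasta", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    rows <- lapply(as.character(seqs), function(s) strsplit(toupper(s), "")[[1]])
    names(rows) <- names(seqs)
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L) abort("No FASTA headers found.")
    ends <- c(hdr[-1] - 1L, length(lines))
    rows <- list()
    for (i in seq_along(hdr)) {
      nm <- sub("^>\\s*", "", lines[hdr[i]])
      body <- lines[seq(hdr[i] + 1L, length.out = max(0L, ends[i] - hdr[i]))]
      tokens <- unlist(strsplit(paste(body, collapse = " "), "\\s+"))
      tokens <- tokens[nzchar(tokens)]
      rows[[nm]] <- parse_pfasta_tokens(tokens, nm)
      if (is.list(rows[[nm]]) && !any(grepl(",", tokens, fixed = TRUE))) {
        rows[[nm]] <- toupper(tokens)
      }
    }
  }
  widths <- vapply(rows, function(r) if (is.character(r)) length(r) else length(r$present),
                   integer(1))
  if (length(unique(widths)) != 1L) {
    abort("Ragged alignment: rows differ in column count.")
  }
  prob_alignment(rows)
}

# ---- BED -----------------------------------------------------------------

#' Read a BED3/BED6 file into a tibble
#'
#' @param path BED file (0-based half-open).
#' @return Tibble with chrom/start/end and, when present, name/score/strand.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cols[seq_len(ncol(x))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  check_intervals(as_tibble(x))
}

#' Write intervals to BED
#'
#' @param x Interval tibble (chrom/start/end plus optional name/score/strand).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  readr::write_tsv(x[keep], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# ---- VCF -----------------------------------------------------------------

#' Read a VCF into a variant tibble
#'
#' Reads CHROM/POS/REF/ALT, the `AA` INFO key when present, and phased or
#' unphased genotypes.  Positions are converted to 0-based offsets; derived
#' and alternate allele counts are taken over all non-missing haplotypes.
#'
#' @param path VCF file (plain text or gzipped).
#' @return A tibble with columns chrom, pos (0-based), ref, alt, aa, ac, an.
#'   The per-haplotype allele matrix (sites x haplotypes, values 0/1/NA) is
#'   attached as attribute `"gt"` when genotypes are present.
#' @export
read_vcf_tbl <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  aa <- stringr::str_match(info, "(?:^|;)AA=([^;]+)")[, 2]
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt = fix$ALT,
    aa = aa
  )
  gt_mat <- NULL
  if (!is.null(v@gt) && ncol(v@gt) > 1L) {
    gt <- v@gt[, -1, drop = FALSE]
    hap <- do.call(rbind, lapply(seq_len(nrow(gt)), function(i) {
      unlist(strsplit(gt[i, ], "[|/]"))
    }))
    hap_num <- suppressWarnings(matrix(as.integer(hap), nrow = nrow(gt)))
    gt_mat <- hap_num
    out$ac <- rowSums(hap_num == 1L, na.rm = TRUE)
    out$an <- rowSums(!is.na(hap_num))
  } else {
    out$ac <- NA_integer_
    out$an <- NA_integer_
  }
  attr(out, "gt") <- gt_mat
  out
}

#' Write a variant tibble as a minimal VCF
#'
#' @param x Tibble with chrom, pos (0-based), ref, alt and optional aa.
#' @param path Output path.
#' @param gt Optional haplotype matrix (sites x haplotypes, 0/1); haplotype
#'   pairs are written as phased diploid genotypes.
#' @return `path`, invisibly.
#' @export
write_vcf_tbl <- function(x, path, gt = attr(x, "gt")) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  ), con)
  info <- if ("aa" %in% names(x)) {
    ifelse(is.na(x$aa), ".", paste0("AA=", x$aa))
  } else rep(".", nrow(x))
  body <- data.frame(
    x$chrom, x$pos + 1L, ".", x$ref, x$alt, ".", "PASS", info,
    stringsAsFactors = FALSE
  )
  header <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  if (!is.null(gt)) {
    if (ncol(gt) %% 2L != 0L) abort("`gt` must hold haplotype pairs (even column count).")
    pair <- matrix(seq_len(ncol(gt)), nrow = 2L)
    gts <- apply(pair, 2, function(p) paste(gt[, p[1]], gt[, p[2]], sep = "|"))
    if (is.null(dim(gts))) gts <- matrix(gts, nrow = 1L)
    body$FORMAT <- "GT"
    body <- cbind(body, gts)
    header <- paste(c(header, "FORMAT",
                      paste0("S", seq_len(ncol(gt) / 2L))), collapse = "\t")
  }
  writeLines(header, con)
  writeLines(do.call(paste, c(unname(as.list(body)), sep = "\t")), con)
  invisible(path)
}

# ---- GTF (CDS features) --------------------------------------------------

#' Read CDS features from a GTF file
#'
#' A thin reader for the columns [extract_4d_sites()] needs.  Uses
#' rtracklayer when installed, else a tab-delimited fallback.
#'
#' @param path GTF file.
#' @return Tibble with chrom, start (0-based), end, strand, frame,
#'   transcript_id.
#' @export
read_cds_gtf <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- as.data.frame(rtracklayer::import(path, format = "gtf"))
    g <- g[g$type == "CDS", ]
    tibble(
      chrom = as.character(g$seqnames),
      start = as.integer(g$start) - 1L,
      end = as.integer(g$end),
      strand = as.character(g$strand),
      frame = as.integer(as.character(g$phase)),
      transcript_id = as.character(g$transcript_id)
    )
  } else {
    x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
    x <- x[x$X3 == "CDS", ]
    tid <- stringr::str_match(x$X9, "transcript_id \"([^\"]+)\"")[, 2]
    tibble(
      chrom = x$X1, start = as.integer(x$X4) - 1L, end = as.integer(x$X5),
      strand = x$X7, frame = as.integer(x$X8), transcript_id = tid
    )
  }
}

# ---- WIG -----------------------------------------------------------------

#' Write a fixed-step WIG track
#'
#' @param values Numeric vector, one value per step.
#' @param chrom Chromosome name.
#' @param start 0-based start of the first step (written 1-based per WIG).
#' @param step Step (and span) in bases.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(values, chrom, start, step, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                     chrom, start + 1L, step, step), con)
  writeLines(format(values, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

# ---- assembly statistics -------------------------------------------------

#' Contig count and N50 of an assembly
#'
#' N50 is the largest length L such that contigs of length >= L together
#' cover at least half the assembly.
#'
#' @param contig_lengths Positive integer vector of contig lengths.
#' @return A tibble with columns `contig_count` and `n50`.
#' @examples
#' assembly_stats(c(5, 4, 3, 2, 1))
#' @export
assembly_stats <- function(contig_lengths) {
  if (length(contig_lengths) == 0L) abort("`contig_lengths` must be non-empty.")
  if (any(contig_lengths <= 0)) abort("Contig lengths must be positive.")
  len <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  i <- which(cumsum(len) >= sum(len) / 2)[1]
  tibble(contig_count = length(len), n50 = len[i])
}
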