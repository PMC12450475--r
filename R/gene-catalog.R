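#' Read gene models from a GTF or BED annotation
#'
#' Builds one record per gene, with `length_bp` equal to the genomic span of
#' the gene's longest transcript (introns included). BED input is treated as
#' one interval per gene (0-based, half-open); GTF input (1-based, inclusive)
#' is consolidated to the longest transcript per gene, ties broken by the
#' lexicographically smallest transcript id.
#'
#' @param path Path to a `.gtf`/`.gff` or `.bed` file.
#' @param format Either `"auto"` (default; decided from the file extension),
#'   `"gtf"` or `"bed"`.
#' @return A tibble with columns `gene_id`, `length_bp`, `chrom`, `start`,
#'   `end`, `strand`. Coordinates are 0-based half-open regardless of the
#'   input dialect, so `length_bp == end - start`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t600\tgA", bed)
#' read_gene_annotation(bed)
#' @export
read_gene_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) {
      abort(paste0("failed to parse ", format, " annotation '", path, "': ",
                   conditionMessage(e)))
    }
  )
  if (length(gr) == 0L) abort(paste0("annotation '", path, "' contains no records"))

  if (format == "bed") {
    d <- as.data.frame(gr)
    out <- tibble(
      gene_id = as.character(d$name %||% paste0("gene_", seq_len(nrow(d)))),
      chrom = as.character(d$seqnames),
      # rtracklayer re-bases BED to 1-based inclusive; convert back
      start = d$start - 1L,
      end = d$end,
      strand = as.character(d$strand)
    )
    out$length_bp <- out$end - out$start
    return(select(out, "gene_id", "length_bp", "chrom", "start", "end", "strand"))
  }

  df <- as_tibble(as.data.frame(gr))
  type_col <- tolower(as.character(df$type %||% ""))
  tx <- df[type_col %in% c("transcript", "mrna"), , drop = FALSE]
  if (nrow(tx) == 0L) {
    # fall back to spans of exon groups per transcript
    ex <- df[type_col == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) abort("GTF contains no transcript or exon features")
    tx <- ex |>
      group_by(.data$gene_id, .data$transcript_id) |>
      summarise(
        seqnames = .data$seqnames[1], strand = .data$strand[1],
        start = min(.data$start), end = max(.data$end), .groups = "drop"
      )
  }
  if (is.null(tx$gene_id)) abort("GTF transcripts carry no gene_id attribute")

  all_genes <- unique(as.character(df$gene_id[!is.na(df$gene_id)]))
  no_tx <- setdiff(all_genes, unique(as.character(tx$gene_id)))
  if (length(no_tx) > 0L) {
    warn(paste0(length(no_tx), " gene(s) without transcripts skipped: ",
                paste(head(no_tx, 5L), collapse = ", ")))
  }

  tx |>
    mutate(
      span = .data$end - .data$start + 1L,
      transcript_id = as.character(.data$transcript_id %||% .data$gene_id)
    ) |>
    group_by(gene_id = as.character(.data$gene_id)) |>
    arrange(dplyr::desc(.data$span), .data$transcript_id, .by_group = TRUE) |>
    summarise(
      length_bp = .data$span[1],
      chrom = as.character(.data$seqnames[1]),
      start0 = .data$start[1] - 1L,  # store 0-based half-open
      end = .data$start[1] - 1L + .data$span[1],
      strand = as.character(.data$strand[1]),
      .groups = "drop"
    ) |>
    dplyr::rename(start = "start0") |>
    select("gene_id", "length_bp", "chrom", "start", "end", "strand")
}

#' Attach expression measurements to gene records
#'
#' @param records Tibble of gene records (`gene_id`, `length_bp`, ...).
#' @param counts Tibble or TSV path with columns `gene_id` and `count`
#'   (reads or RPM; the unit cancels when weights are normalized).
#' @param missing How to treat genes absent from the count table:
#'   `"zero"` (default) assigns 0, `"drop"` removes them.
#' @return `records` with an `expression_raw` column.
#' @export
add_expression <- function(records, counts, missing = c("zero", "drop")) {
  missing <- match.arg(missing)
  if (is.character(counts)) {
    counts <- readr::read_tsv(counts, show_col_types = FALSE)
  }
  counts <- as_tibble(counts)
  if (!all(c("gene_id", "count") %in% names(counts))) {
    abort("count table needs columns 'gene_id' and 'count'")
  }
  if (any(counts$count < 0, na.rm = TRUE)) abort("negative expression counts")
  out <- left_join(records, select(counts, "gene_id", "count"), by = "gene_id")
  out <- dplyr::rename(out, expression_raw = "count")
  if (missing == "drop") {
    out <- filter(out, !is.na(.data$expression_raw))
  } else {
    out$expression_raw[is.na(out$expression_raw)] <- 0
  }
  out
}

#' Filter gene records by length and expression
#'
#' Applies the catalog inclusion rules: drop genes shorter than
#' `min_length_bp` (default 5 kb), optionally drop genes longer than
#' `max_length_bp` (750 kb in the long-gene sensitivity filter), and
#' optionally drop non-expressed genes (0 reads/RPM).
#'
#' @param records Tibble with `length_bp` and (if `require_expressed`)
#'   `expression_raw`.
#' @param min_length_bp Minimum gene length in bp, inclusive.
#' @param max_length_bp Optional maximum gene length in bp, inclusive.
#' @param require_expressed Drop genes with `expression_raw == 0`?
#' @param quiet Suppress the per-rule removal counts message.
#' @return The filtered tibble; removal counts per rule are attached as the
#'   `"removed"` attribute and reported via a message.
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("a", "b", "c"), length_bp = c(4999, 6000, 800000),
#'   expression_raw = c(5, 0, 2)
#' )
#' filter_genes(genes, max_length_bp = 750000, require_expressed = TRUE)
#' @export
filter_genes <- function(records, min_length_bp = 5000, max_length_bp = NULL,
                         require_expressed = FALSE, quiet = FALSE) {
  records <- as_tibble(records)
  removed <- c(too_short = 0L, too_long = 0L, not_expressed = 0L)
  keep <- records$length_bp >= min_length_bp
  removed[["too_short"]] <- sum(!keep)
  if (!is.null(max_length_bp)) {
    long <- records$length_bp > max_length_bp
    removed[["too_long"]] <- sum(keep & long)
    keep <- keep & !long
  }
  if (isTRUE(require_expressed)) {
    if (is.null(records$expression_raw)) {
      abort("require_expressed = TRUE but records carry no 'expression_raw'")
    }
    unexpr <- records$expression_raw <= 0
    removed[["not_expressed"]] <- sum(keep & unexpr)
    keep <- keep & !unexpr
  }
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) abort("all genes removed by filtering; catalog would be empty")
  if (!quiet) {
    inform(sprintf("filter_genes: removed %d too short, %d too long, %d not expressed; %d retained",
                   removed[["too_short"]], removed[["too_long"]],
                   removed[["not_expressed"]], nrow(out)))
  }
  attr(out, "removed") <- removed
  out
}

#' Build a weighted gene catalog
#'
#' Computes, for each gene, the expression weight
#' \eqn{\alpha_i = e_i / \sum_j e_j} (so \eqn{\sum \alpha = 1}) and the
#' per-allele transcribed-strand hit probability \eqn{q_i = l_i / (4L)},
#' where \eqn{l_i} is the gene length and \eqn{L} the haploid genome length.
#' The factor 4 counts two alleles times two strands: a uniformly placed
#' lesion silences an allele only when it lands on that allele's transcribed
#' strand.
#'
#' @param records Tibble with `gene_id`, `length_bp`, `expression_raw`.
#' @param genome_length Haploid genome length L in bp.
#' @return A `gene_catalog`: a tibble with columns `gene_id`, `length_bp`,
#'   `expression_raw`, `alpha`, `q` and attribute `genome_length`.
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("g1", "g2"), length_bp = c(1e5, 5e4),
#'   expression_raw = c(30, 10)
#' )
#' cat <- build_catalog(genes, genome_length = 3.2e9)
#' cat$alpha  # 0.75 0.25
#' @export
build_catalog <- function(records, genome_length) {
  records <- as_tibble(records)
  stopifnot(is.numeric(genome_length), length(genome_length) == 1L, genome_length > 0)
  need <- c("gene_id", "length_bp", "expression_raw")
  if (!all(need %in% names(records))) {
    abort(paste0("records need columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(records$gene_id)) abort("gene_ids are not unique")
  if (any(records$length_bp < 1)) abort("gene lengths must be >= 1 bp")
  if (any(records$expression_raw < 0)) abort("negative expression")
  total_expr <- sum(records$expression_raw)
  if (total_expr <= 0) abort("all-zero expression: weights undefined")
  if (sum(as.numeric(records$length_bp)) > genome_length) {
    abort(paste0("sum of gene lengths exceeds the genome length L; the ",
                 "uniform-placement simulator requires total gene span <= L"))
  }
  out <- records |>
    mutate(
      alpha = .data$expression_raw / total_expr,
      q = .data$length_bp / (4 * genome_length)
    )
  new_gene_catalog(out, genome_length)
}

new_gene_catalog <- function(df, genome_length) {
  out <- as_tibble(df)
  attr(out, "genome_length") <- genome_length
  class(out) <- c("gene_catalog", class(out))
  out
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d genes, L = %s bp, sum(alpha) = %.6f\n",
              nrow(x), format(genome_length(x), big.mark = ","), sum(x$alpha)))
  NextMethod()
}

#' Haploid genome length of a catalog
#' @param catalog A `gene_catalog`.
#' @return Genome length L in bp.
#' @export
genome_length <- function(catalog) {
  L <- attr(catalog, "genome_length")
  if (is.null(L)) abort("not a gene_catalog: missing genome_length attribute")
  L
}

#' Validate gene-catalog invariants
#'
#' Checks that weights sum to one, hit probabilities match `length_bp/(4L)`
#' and lie in (0, 1), gene ids are unique, and the total gene span fits in
#' the genome.
#'
#' @param catalog A `gene_catalog`.
#' @return Invisibly `TRUE`; aborts with the violated invariant otherwise.
#' @export
validate_catalog <- function(catalog) {
  L <- genome_length(catalog)
  if (abs(sum(catalog$alpha) - 1) > 1e-9) abort("sum(alpha) != 1")
  if (any(catalog$q <= 0) || any(catalog$q >= 1)) abort("q out of (0, 1)")
  if (max(abs(catalog$q - catalog$length_bp / (4 * L))) > 1e-12) {
    abort("q inconsistent with length_bp/(4L)")
  }
  if (anyDuplicated(catalog$gene_id)) abort("duplicate gene_ids")
  if (sum(as.numeric(catalog$length_bp)) > L) abort("total gene span exceeds L")
  invisible(TRUE)
}

#' Write / read a gene catalog as TSV
#'
#' The genome length travels in a `# genome_length=` header comment so a
#' round trip restores the full catalog.
#'
#' @param catalog A `gene_catalog`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  body <- readr::format_tsv(as_tibble(as.data.frame(catalog)))
  writeLines(c(
    sprintf("# genome_length=%.0f", genome_length(catalog)),
    strsplit(body, "\n", fixed = TRUE)[[1]]
  ), path)
  invisible(path)
}

#' @rdname write_catalog
#' @param genome_length Override for the genome length when the header
#'   comment is absent.
#' @export
read_catalog <- function(path, genome_length = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^# genome_length=", first)) {
    genome_length <- as.numeric(sub("^# genome_length=", "", first))
  }
  if (is.null(genome_length)) abort("genome_length not in file header; supply it")
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  build_catalog(select(df, "gene_id", "length_bp", "expression_raw"),
                genome_length = genome_length)
}
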