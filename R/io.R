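# ---- TSV dialect -----------------------------------------------------------
# All interchange files are tab-separated with '#'-prefixed header comment
# lines naming the producing stage, the config hash (when available) and the
# column schema, followed by a regular header row. Readers skip '#' lines.

.write_header <- function(path, stage, columns, config_hash = NULL) {
  lines <- c(
    sprintf("# spliceswitch stage=%s", stage),
    if (!is.null(config_hash)) sprintf("# config_hash=%s", config_hash),
    sprintf("# columns=%s", paste(columns, collapse = ","))
  )
  writeLines(lines, path)
}

.write_stage_tsv <- function(x, path, stage, config_hash = NULL) {
  .write_header(path, stage, names(x), config_hash)
  suppressWarnings(
    utils::write.table(x, path, append = TRUE, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  )
  invisible(path)
}

# Number of leading comment lines, used to report real file line numbers in
# schema errors (comments are only ever written at the top of a file).
.n_comment_lines <- function(path) {
  head_lines <- readLines(path, n = 100L)
  n <- 0L
  for (ln in head_lines) {
    if (startsWith(ln, "#")) n <- n + 1L else break
  }
  n
}

.schema_error <- function(path, rows, offset, what) {
  stop(sprintf("schema error in %s (line %s): %s", path,
               paste(rows + offset, collapse = ", "), what),
       call. = FALSE)
}

.read_stage_tsv <- function(path, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE)
}

# ---- event catalog ---------------------------------------------------------

.validate_catalog <- function(df, path = "<catalog>", offset = 0L) {
  req <- c("event_id", "gene_id", "category", "chrom", "strand", "segments",
           "L_inc", "L_exc")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("catalog is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$category %in% SPLICE_CATEGORIES)
  if (length(bad)) {
    .schema_error(path, bad, offset,
                  paste("unknown category token:",
                        paste(unique(df$category[bad]), collapse = ", ")))
  }
  dup <- which(duplicated(df$event_id))
  if (length(dup)) .schema_error(path, dup, offset, "duplicate event_id")
  bad <- which(df$L_inc < 1 | df$L_exc < 1 | is.na(df$L_inc) |
                 is.na(df$L_exc))
  if (length(bad)) .schema_error(path, bad, offset,
                                 "effective lengths must be >= 1")
  seg_ok <- vapply(strsplit(df$segments, ";", fixed = TRUE), function(s) {
    m <- regmatches(s, regexec("^([0-9]+)-([0-9]+)$", s))
    length(s) >= 1 && all(vapply(m, length, integer(1)) == 3) &&
      all(vapply(m, function(p) as.numeric(p[2]) <= as.numeric(p[3]),
                 logical(1)))
  }, logical(1))
  if (any(!seg_ok)) {
    .schema_error(path, which(!seg_ok), offset,
                  "segments must be non-empty 'start-end' pairs with start <= end")
  }
  invisible(df)
}

#' Read / write a splice-event catalog TSV
#'
#' The catalog TSV holds one row per event with columns `event_id`,
#' `gene_id`, `category`, `chrom`, `strand`, `segments` (semicolon-separated
#' 1-based inclusive `start-end` pairs), `L_inc`, `L_exc`. Files start with
#' `#` comment lines naming the producing stage and schema. Reading
#' validates categories, event-id uniqueness, lengths and segment syntax,
#' reporting offending file line numbers.
#'
#' @param path File path.
#' @param catalog Catalog tibble to write.
#' @param config_hash Optional configuration hash recorded in the header.
#' @return `read_event_catalog()` returns the validated catalog tibble;
#'   `write_event_catalog()` returns `path` invisibly.
#' @export
read_event_catalog <- function(path) {
  df <- .read_stage_tsv(path, readr::cols(
    event_id = "c", gene_id = "c", category = "c", chrom = "c",
    strand = "c", segments = "c", L_inc = "i", L_exc = "i"
  ))
  .validate_catalog(df, path, offset = .n_comment_lines(path) + 1L)
}

#' @rdname read_event_catalog
#' @export
write_event_catalog <- function(catalog, path, config_hash = NULL) {
  .validate_catalog(catalog)
  .write_stage_tsv(catalog, path, "catalog", config_hash)
}

#' Export a catalog as GFF3
#'
#' Writes one feature per event segment (1-based inclusive coordinates, as
#' stored), with `event_id`, `gene_id` and `category` carried in the
#' attributes column. Requires the rtracklayer and GenomicRanges packages.
#'
#' @param catalog Catalog tibble.
#' @param path Output `.gff3` path.
#' @return `path`, invisibly.
#' @export
write_catalog_gff3 <- function(catalog, path) {
  for (pkg in c("GenomicRanges", "IRanges", "rtracklayer")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package '", pkg, "' is required for GFF3 export", call. = FALSE)
    }
  }
  .validate_catalog(catalog)
  segs <- strsplit(catalog$segments, ";", fixed = TRUE)
  n_seg <- lengths(segs)
  flat <- unlist(segs)
  start <- as.integer(sub("-.*", "", flat))
  end <- as.integer(sub(".*-", "", flat))
  i <- rep(seq_len(nrow(catalog)), n_seg)
  gr <- GenomicRanges::GRanges(
    seqnames = catalog$chrom[i],
    ranges = IRanges::IRanges(start = start, end = end),
    strand = catalog$strand[i]
  )
  gr$source <- "spliceswitch"
  gr$type <- "exonic_part"
  gr$ID <- sprintf("%s.seg%d", catalog$event_id[i],
                   unlist(lapply(n_seg, seq_len)))
  gr$event_id <- catalog$event_id[i]
  gr$gene_id <- catalog$gene_id[i]
  gr$category <- catalog$category[i]
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

# ---- counts ----------------------------------------------------------------

.validate_counts <- function(df, path = "<counts>", offset = 0L) {
  req <- c("event_id", "sample_id", "condition", "replicate", "n_inc",
           "n_exc")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("counts table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(df$n_inc < 0 | df$n_exc < 0 | is.na(df$n_inc) |
                 is.na(df$n_exc))
  if (length(bad)) .schema_error(path, bad, offset,
                                 "read counts must be non-negative")
  dup <- which(duplicated(df[, c("event_id", "sample_id")]))
  if (length(dup)) {
    .schema_error(path, dup, offset, "duplicate (event_id, sample_id) pair")
  }
  invisible(df)
}

#' Read / write a junction-count TSV
#'
#' One row per event and sample: `event_id`, `sample_id`, `condition`,
#' `replicate`, `n_inc`, `n_exc`. Reading validates non-negative counts and
#' (event, sample) uniqueness with file line numbers.
#'
#' @param path File path.
#' @param counts Counts tibble to write.
#' @param config_hash Optional configuration hash for the header.
#' @return The validated counts tibble, or `path` invisibly for the writer.
#' @export
read_event_counts <- function(path) {
  df <- .read_stage_tsv(path, readr::cols(
    event_id = "c", sample_id = "c", condition = "c", replicate = "i",
    n_inc = "i", n_exc = "i"
  ))
  .validate_counts(df, path, offset = .n_comment_lines(path) + 1L)
}

#' @rdname read_event_counts
#' @export
write_event_counts <- function(counts, path, config_hash = NULL) {
  .validate_counts(counts)
  .write_stage_tsv(counts, path, "counts", config_hash)
}

# ---- truth -----------------------------------------------------------------

#' Read / write a simulation ground-truth TSV
#'
#' Mirrors the tibble returned by [simulate_truth()] (per-condition true
#' PSI, differential/switch flags, signed effects, substrate labels).
#'
#' @param path File path.
#' @param truth Truth tibble to write.
#' @param config_hash Optional configuration hash for the header.
#' @export
read_sim_truth <- function(path) {
  .read_stage_tsv(path, readr::cols(
    event_id = "c", gene_id = "c", category = "c",
    .default = readr::col_guess()
  ))
}

#' @rdname read_sim_truth
#' @export
write_sim_truth <- function(truth, path, config_hash = NULL) {
  .write_stage_tsv(truth, path, "truth", config_hash)
}

# ---- contrast --------------------------------------------------------------

#' Read / write a differential-calling contrast TSV
#'
#' The interchange format between the calling stage and the downstream
#' composition, enrichment and switch analyses. The list-column of
#' per-replicate delta-PSI values is serialised as a comma-joined string and
#' parsed back on reading, so a write/read round trip reproduces the
#' original table. Contrast metadata (label, conditions, thresholds) is
#' stored in additional header comments.
#'
#' @param path File path.
#' @param contrast `splice_contrast` tibble to write.
#' @param config_hash Optional configuration hash for the header.
#' @return `read_contrast()` returns a `splice_contrast` tibble.
#' @export
write_contrast <- function(contrast, path, config_hash = NULL) {
  x <- tibble::as_tibble(contrast)
  x$replicate_delta_psi <- vapply(
    x$replicate_delta_psi,
    function(v) paste(formatC(v, digits = 17, format = "g"), collapse = ","),
    character(1)
  )
  cond <- attr(contrast, "conditions")
  lines <- c(
    "# spliceswitch stage=contrast",
    if (!is.null(config_hash)) sprintf("# config_hash=%s", config_hash),
    sprintf("# contrast_label=%s", attr(contrast, "contrast_label")),
    sprintf("# condition_a=%s", cond[["a"]]),
    sprintf("# condition_b=%s", cond[["b"]]),
    "# delta_psi orientation: condition_b minus condition_a",
    sprintf("# bf_threshold=%s", format(attr(contrast, "bf_threshold"))),
    sprintf("# min_info=%s", format(attr(contrast, "min_info"))),
    sprintf("# columns=%s", paste(names(x), collapse = ","))
  )
  writeLines(lines, path)
  suppressWarnings(
    utils::write.table(x, path, append = TRUE, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  )
  invisible(path)
}

#' @rdname write_contrast
#' @export
read_contrast <- function(path) {
  head_lines <- readLines(path, n = 20L)
  meta <- function(key, default = NA_character_) {
    hit <- grep(sprintf("^# %s=", key), head_lines, value = TRUE)
    if (length(hit)) sub(sprintf("^# %s=", key), "", hit[1]) else default
  }
  df <- .read_stage_tsv(path, readr::cols(
    event_id = "c", gene_id = "c", category = "c",
    n_total_a = "i", n_total_b = "i", testable = "l",
    psi_a = "d", psi_b = "d", bf = "d", delta_psi = "d",
    replicate_delta_psi = "c", consistent = "l", significant = "l",
    direction = "c"
  ))
  df$replicate_delta_psi <- lapply(
    strsplit(df$replicate_delta_psi, ",", fixed = TRUE), as.numeric
  )
  new_splice_contrast(
    df,
    contrast_label = meta("contrast_label"),
    conditions = c(a = meta("condition_a"), b = meta("condition_b")),
    bf_threshold = as.numeric(meta("bf_threshold", "20")),
    min_info = as.numeric(meta("min_info", "10"))
  )
}

# ---- gene sets (GMT) -------------------------------------------------------

#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated with one set per line: set name, description, then
#' one gene id per remaining field. `read_gene_sets()` returns a tibble with
#' a `genes` list-column, directly usable by [hypergeometric_enrichment()]
#' and [ks_delta_psi()]; rows with fewer than three fields are schema errors
#' reported with their line numbers.
#'
#' @param path GMT file path.
#' @param sets Tibble (`set_name`, `description`, `genes` list-column) or
#'   named list of gene-id vectors.
#' @return Tibble with columns `set_name`, `description`, `genes`
#'   (list-column), `n_genes`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad)) {
    .schema_error(path, which(keep)[bad], 0L,
                  "GMT lines need at least set name, description and one gene")
  }
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  nm <- vapply(fields, `[`, character(1), 1)
  dup <- which(duplicated(nm))
  if (length(dup)) .schema_error(path, which(keep)[dup], 0L,
                                 "duplicate set name")
  tibble::tibble(
    set_name = nm,
    description = vapply(fields, `[`, character(1), 2),
    genes = genes,
    n_genes = lengths(genes)
  )
}

#' @rdname read_gene_sets
#' @export
write_gene_sets <- function(sets, path) {
  if (!is.data.frame(sets)) {
    sets <- tibble::tibble(
      set_name = names(sets),
      description = names(sets),
      genes = unname(sets)
    )
  }
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_name[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
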