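# Tabular and genomic-format IO shared by every pipeline stage.
#
# Conventions: genotype classes are unordered allele pairs stored as
# "A:G" with alleles sorted; all genomic coordinates are 0-based
# half-open internally, 1-based only at the VCF boundary.

MISSING_TOKENS <- c("", "NA", "-", "./.")

#' Normalize biallelic genotype call labels
#'
#' KASP and similar exports are unphased, so `"G:A"` and `"A:G"` denote the
#' same genotype class. Calls are normalized to the sorted allele pair joined
#' by `":"`; single-allele calls (`"A"`) are read as homozygous (`"A:A"`).
#' Missing tokens (`""`, `"NA"`, `"-"`, `"./."`) map to `NA`.
#'
#' @param x character vector of raw call labels.
#' @return character vector of normalized class labels, `NA` for missing.
#' @examples
#' normalize_call(c("G:A", "A:G", "A", "-"))
#' @export
normalize_call <- function(x) {
  x <- trimws(as.character(x))
  # normalize each distinct label once, then map back
  ux <- unique(x)
  norm <- vapply(ux, function(u) {
    if (is.na(u) || u %in% MISSING_TOKENS) return(NA_character_)
    p <- strsplit(u, ":", fixed = TRUE)[[1]]
    p <- p[nzchar(p)]
    if (length(p) == 1L) p <- c(p, p)
    if (length(p) != 2L) {
      stop("malformed genotype call (expected 1 or 2 alleles): ", u,
           call. = FALSE)
    }
    paste(sort(p), collapse = ":")
  }, character(1))
  unname(norm[match(x, ux)])
}

#' Alleles of a normalized genotype class
#' @param class normalized class label such as `"A:G"`.
#' @return character vector of the (1 or 2 distinct) alleles.
#' @keywords internal
class_alleles <- function(class) {
  unique(strsplit(class, ":", fixed = TRUE)[[1]])
}

#' Is a normalized class heterozygous?
#' @param class character vector of normalized class labels.
#' @return logical vector.
#' @export
is_heterozygous <- function(class) {
  vapply(class, function(cl) {
    if (is.na(cl)) return(NA)
    length(class_alleles(cl)) == 2L
  }, logical(1), USE.NAMES = FALSE)
}

#' Construct a hybrids x markers genotype table
#'
#' @param calls character matrix (hybrids in rows, markers in columns) of
#'   genotype call labels; normalized internally. `rownames` are hybrid ids,
#'   `colnames` marker ids.
#' @param population optional character vector of per-hybrid cross labels.
#' @return an object of class `genotype_table` with elements `calls`
#'   (normalized matrix), `hybrid_ids`, `marker_ids`, `population`.
#' @export
genotype_table <- function(calls, population = NULL) {
  stopifnot(is.matrix(calls))
  hybrid_ids <- rownames(calls)
  marker_ids <- colnames(calls)
  if (is.null(marker_ids) && ncol(calls) == 0L) marker_ids <- character(0)
  if (is.null(hybrid_ids) || is.null(marker_ids)) {
    stop("genotype call matrix must have hybrid row names and marker column names")
  }
  if (anyDuplicated(hybrid_ids)) {
    stop("duplicate hybrid id: ", hybrid_ids[duplicated(hybrid_ids)][1])
  }
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker id: ", marker_ids[duplicated(marker_ids)][1])
  }
  norm <- matrix(normalize_call(calls), nrow = nrow(calls),
                 dimnames = dimnames(calls))
  # a biallelic marker may expose at most 2 distinct alleles
  for (m in marker_ids) {
    ucls <- unique(norm[, m])
    alleles <- unique(unlist(strsplit(ucls[!is.na(ucls)], ":", fixed = TRUE)))
    if (length(alleles) > 2L) {
      stop("marker ", m, " shows ", length(alleles),
           " alleles (", paste(sort(alleles), collapse = ","),
           "); at most 2 allowed")
    }
  }
  if (!is.null(population)) {
    stopifnot(length(population) == length(hybrid_ids))
    population <- as.character(population)
    names(population) <- hybrid_ids
  }
  structure(list(calls = norm, hybrid_ids = hybrid_ids,
                 marker_ids = marker_ids, population = population),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$hybrid_ids), "hybrids x",
      length(x$marker_ids), "markers;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

# sniff comma vs tab from the header line; explicit sep wins
detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_chr <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = detect_sep(path, sep), header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "", fileEncoding = "UTF-8")
}

#' Read a hybrids x markers genotype table from TSV/CSV
#'
#' The first column (named `hybrid_id`) carries hybrid identifiers, an
#' optional `population` column carries the cross label, and every remaining
#' column is a marker whose cells are `"X:Y"` calls, single-allele
#' homozygote calls `"X"`, or missing tokens. Tab/comma dialect is
#' auto-detected from the header.
#'
#' @param path file path.
#' @param sep optional field separator overriding auto-detection.
#' @param quiet suppress the parse report message.
#' @return a [genotype_table].
#' @export
read_genotype_table <- function(path, sep = NULL, quiet = FALSE) {
  df <- read_delim_chr(path, sep)
  if (!"hybrid_id" %in% names(df)) names(df)[1] <- "hybrid_id"
  if (anyDuplicated(df$hybrid_id)) {
    stop("duplicate hybrid id: ", df$hybrid_id[duplicated(df$hybrid_id)][1])
  }
  population <- NULL
  if ("population" %in% names(df)) population <- df$population
  marker_cols <- setdiff(names(df), c("hybrid_id", "population"))
  if (length(marker_cols) == 0L) stop("no marker columns found in ", path)
  calls <- as.matrix(df[marker_cols])
  rownames(calls) <- df$hybrid_id
  gt <- genotype_table(calls, population = population)
  if (!quiet) {
    message(sprintf("read %d hybrids x %d markers (%.1f%% missing calls) from %s",
                    length(gt$hybrid_ids), length(gt$marker_ids),
                    100 * mean(is.na(gt$calls)), path))
  }
  gt
}

#' Write a genotype table to TSV
#' @param gt a [genotype_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path) {
  df <- data.frame(hybrid_id = gt$hybrid_ids, stringsAsFactors = FALSE)
  if (!is.null(gt$population)) df$population <- unname(gt$population)
  calls <- gt$calls
  calls[is.na(calls)] <- "NA"
  df <- cbind(df, as.data.frame(calls, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Expected columns: `hybrid_id`, `trait`, `opv` (months, non-negative) and
#' optionally `year`.
#'
#' @param path file path.
#' @param sep optional separator override.
#' @param max_month upper bound for observed phenotype values.
#' @return data.frame with columns `hybrid_id`, `trait`, `opv`, `year`.
#' @export
read_phenotype_table <- function(path, sep = NULL, max_month = 6) {
  df <- read_delim_chr(path, sep)
  req <- c("hybrid_id", "trait", "opv")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$opv <- as.numeric(df$opv)
  if (anyNA(df$opv)) stop("non-numeric opv value in ", path)
  if (any(df$opv < 0 | df$opv > max_month)) {
    stop("opv outside [0, ", max_month, "] in ", path)
  }
  df$year <- if ("year" %in% names(df)) as.integer(df$year) else NA_integer_
  key <- paste(df$hybrid_id, df$trait, df$year)
  if (anyDuplicated(key)) {
    stop("duplicate (hybrid, trait, year) record: ", key[duplicated(key)][1])
  }
  df[c("hybrid_id", "trait", "opv", "year")]
}

#' Write a phenotype table to TSV
#' @param df phenotype data.frame as returned by [read_phenotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format cold-storage measurement table
#'
#' Expected columns: `hybrid_id`, `trait` (`firmness`/`crispness`), `month`
#' (integer >= 0), `value` (kg/cm^2, >= 0). Duplicate
#' (hybrid, trait, month) rows are technical replicates and are averaged;
#' each series is returned sorted by month.
#'
#' @param path file path.
#' @param sep optional separator override.
#' @return list of [storage_series] objects.
#' @export
read_storage_table <- function(path, sep = NULL) {
  df <- read_delim_chr(path, sep)
  req <- c("hybrid_id", "trait", "month", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("storage table missing column(s): ",
                         paste(miss, collapse = ", "))
  month_num <- as.numeric(df$month)
  if (anyNA(month_num) || any(month_num != round(month_num))) {
    stop("non-integer month in ", path)
  }
  df$month <- as.integer(month_num)
  df$value <- as.numeric(df$value)
  if (anyNA(df$value)) stop("non-numeric value in ", path)
  if (any(df$value < 0)) stop("negative measurement value in ", path)
  if (any(df$month < 0)) stop("negative month in ", path)
  out <- list()
  for (key in unique(paste(df$hybrid_id, df$trait, sep = "\r"))) {
    id_trait <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- df[df$hybrid_id == id_trait[1] & df$trait == id_trait[2], ]
    means <- tapply(sub$value, sub$month, mean)
    months <- as.integer(names(means))
    ord <- order(months)
    out[[length(out) + 1L]] <- storage_series(
      hybrid_id = id_trait[1], trait = id_trait[2],
      months = months[ord], values = unname(means)[ord])
  }
  out
}

#' Read genomic intervals from a BED file
#'
#' Three or more whitespace-separated columns; coordinates are kept 0-based
#' half-open. The 4th column, when present, becomes the interval label.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `label`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3L) stop("malformed BED line ", i, ": fewer than 3 fields")
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) stop("malformed BED line ", i,
                                         ": non-numeric coordinate")
    if (start < 0 || start >= end) stop("malformed BED line ", i,
                                        ": need 0 <= start < end")
    data.frame(chrom = f[1], start = start, end = end,
               label = if (length(f) >= 4L) f[4] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write genomic intervals to BED
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   `label` (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[c("chrom", "start", "end")]
  if (!is.null(intervals$label)) cols$label <- intervals$label
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF subset
#'
#' Parses only `CHROM`, `POS`, `REF`, `ALT` and an optional `INFO` field whose
#' `key=value` pairs may carry `gene`, `region`
#' (`promoter`/`CDS_domain`/`CDS_other`/`other`), `cis` and `domain`
#' disruption flags (0/1). `POS` is converted from 1-based to the internal
#' 0-based convention.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `pos0`, `ref`, `alt`, `gene_id`,
#'   `region`, `disrupts_cis_element`, `disrupts_domain`.
#' @export
read_minimal_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  recs <- lapply(body_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop("malformed VCF line ", i, ": fewer than 5 fields")
    pos <- suppressWarnings(as.numeric(f[2]))
    if (is.na(pos) || pos < 1) stop("malformed VCF line ", i, ": bad POS")
    info <- if (length(f) >= 8L) f[8] else "."
    kv <- list()
    if (info != ".") {
      for (pair in strsplit(info, ";", fixed = TRUE)[[1]]) {
        eq <- strsplit(pair, "=", fixed = TRUE)[[1]]
        if (length(eq) == 2L) kv[[eq[1]]] <- eq[2]
      }
    }
    data.frame(chrom = f[1], pos0 = pos - 1, ref = f[4], alt = f[5],
               gene_id = if (is.null(kv$gene)) NA_character_ else kv$gene,
               region = if (is.null(kv$region)) "other" else kv$region,
               disrupts_cis_element = identical(kv$cis, "1"),
               disrupts_domain = identical(kv$domain, "1"),
               stringsAsFactors = FALSE)
  })
  if (!length(recs)) {
    return(data.frame(chrom = character(), pos0 = numeric(), ref = character(),
                      alt = character(), gene_id = character(),
                      region = character(), disrupts_cis_element = logical(),
                      disrupts_domain = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

#' Write a minimal VCF
#' @param variants data.frame with `chrom`, `pos0`, `ref`, `alt` and optional
#'   `gene_id`, `region`, `disrupts_cis_element`, `disrupts_domain`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_minimal_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=gene,Number=1,Type=String,Description=\"Gene id\">",
               "##INFO=<ID=region,Number=1,Type=String,Description=\"promoter|CDS_domain|CDS_other|other\">",
               "##INFO=<ID=cis,Number=1,Type=Integer,Description=\"Disrupts cis-element\">",
               "##INFO=<ID=domain,Number=1,Type=Integer,Description=\"Disrupts protein domain\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    info <- sprintf("gene=%s;region=%s;cis=%d;domain=%d",
                    variants$gene_id, variants$region,
                    as.integer(variants$disrupts_cis_element),
                    as.integer(variants$disrupts_domain))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       variants$chrom, as.integer(variants$pos0) + 1L,
                       variants$ref, variants$alt, info), con)
  }
  invisible(path)
}

#' Serialize a fitted GAP model to JSON
#' @param model a `gap_model` (see [gap_fit()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gap_model <- function(model, path) {
  stopifnot(inherits(model, "gap_model"))
  payload <- list(
    format = "gapred_model",
    version = 1L,
    trait = model$trait,
    overall_mean = model$overall_mean,
    training_ids = model$training_ids,
    min_class_n = model$min_class_n,
    effects = model$effects)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Deserialize a GAP model written by [write_gap_model()]
#' @param path JSON path.
#' @return a `gap_model`.
#' @export
read_gap_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "gapred_model")) {
    stop("not a gapred model file: ", path)
  }
  effects <- lapply(payload$effects, function(e) {
    e$classes <- as.data.frame(e$classes, stringsAsFactors = FALSE)
    e
  })
  structure(list(trait = payload$trait,
                 overall_mean = payload$overall_mean,
                 effects = effects,
                 training_ids = payload$training_ids,
                 min_class_n = payload$min_class_n),
            class = "gap_model")
}
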