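#' Import raw xPONENT 3.1 exports
#'
#' Reads the two raw CSV layouts produced by xPONENT 3.1:
#'
#' * `fluorescence` — a single sectioned file: header metadata lines
#'   followed by named data blocks, each introduced by a line whose first
#'   field is `DataType:` (e.g. `Median`, `Count`, `Net MFI`), a column
#'   header row and data rows. Block names are accepted generically. The
#'   delimiter is sniffed between comma and semicolon and a UTF-8 byte
#'   order mark is tolerated. Lines that do not fit the active block are
#'   collected (with their line numbers) in the bundle's `problems`, never
#'   silently dropped.
#' * `bead` — one CSV per analyte with bead-level rows; all files are
#'   merged into a single record table, each row carrying its source file
#'   and analyte.
#'
#' A directory previously written by [lum_export()] can also be re-imported
#' (round trip).
#'
#' @param path For `fluorescence`: one sectioned CSV file or an export
#'   directory. For `bead`: a character vector of CSV files, a directory of
#'   them, or a `.csv.gz` archive written by [lum_export()].
#' @param kind `"fluorescence"` or `"bead"`.
#' @return An object of class `xponent_bundle`: list with `kind`,
#'   `metadata` (key/value tibble), `blocks` (named list of tibbles;
#'   fluorescence kind), `bead_records` (merged tibble; bead kind) and
#'   `problems`.
#' @export
lum_import <- function(path, kind = c("fluorescence", "bead")) {
  kind <- match.arg(kind)
  if (kind == "bead") {
    return(import_bead(path))
  }
  if (length(path) == 1 && dir.exists(path)) {
    return(import_fluorescence_dir(path))
  }
  import_fluorescence_file(path)
}

new_xponent_bundle <- function(kind, metadata, blocks = NULL,
                               bead_records = NULL, problems = NULL) {
  if (is.null(problems)) {
    problems <- tibble::tibble(line = integer(), content = character())
  }
  structure(list(kind = kind, metadata = metadata, blocks = blocks,
                 bead_records = bead_records, problems = problems),
            class = "xponent_bundle")
}

#' @export
print.xponent_bundle <- function(x, ...) {
  cat("<xponent_bundle ", x$kind, ">\n", sep = "")
  if (x$kind == "fluorescence") {
    cat("  blocks:", paste(names(x$blocks), collapse = ", "), "\n")
  } else {
    cat("  bead records:", nrow(x$bead_records), "\n")
  }
  cat("  metadata fields:", nrow(x$metadata),
      " problem lines:", nrow(x$problems), "\n")
  invisible(x)
}

sniff_delim <- function(lines) {
  if (sum(lengths(gregexpr(";", lines, fixed = TRUE))) >
      sum(lengths(gregexpr(",", lines, fixed = TRUE)))) ";" else ","
}

split_fields <- function(line, delim) {
  scan(text = line, what = character(), sep = delim, quiet = TRUE,
       strip.white = FALSE, quote = "\"")
}

import_fluorescence_file <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "beadcal_parse_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines)) lines[1] <- sub("^﻿", "", lines[1])
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) {
    rlang::abort(paste0("empty or blank file: ", path),
                 class = "beadcal_parse_error")
  }
  delim <- sniff_delim(lines[nonblank])
  is_block <- startsWith(trimws(lines), "DataType:")
  first_block <- if (any(is_block)) which(is_block)[1] else NA_integer_
  if (is.na(first_block)) {
    rlang::abort(
      sprintf("unrecognized layout: no 'DataType:' block found (line %d: %s)",
              nonblank[1], substr(lines[nonblank[1]], 1, 60)),
      class = "beadcal_parse_error"
    )
  }

  meta_lines <- lines[seq_len(first_block - 1)]
  meta_lines <- meta_lines[trimws(meta_lines) != ""]
  metadata <- purrr::map_dfr(meta_lines, function(l) {
    f <- split_fields(l, delim)
    f <- f[f != "" | seq_along(f) <= 2]
    tibble::tibble(key = f[1],
                   value = paste(f[-1][f[-1] != ""], collapse = " "))
  })

  blocks <- list()
  problems <- list()
  starts <- which(is_block)
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    head_line <- lines[starts[i]]
    f <- split_fields(head_line, delim)
    label <- if (length(f) >= 2 && trimws(f[2]) != "") {
      trimws(f[2])
    } else {
      trimws(sub("^DataType:", "", head_line))
    }
    body <- lines[seq(starts[i] + 1L, bounds[i + 1] - 1L)]
    body_no <- seq(starts[i] + 1L, bounds[i + 1] - 1L)
    keep <- trimws(body) != ""
    body <- body[keep]
    body_no <- body_no[keep]
    if (!length(body)) next
    header <- split_fields(body[1], delim)
    rows <- lapply(body[-1], split_fields, delim = delim)
    okrow <- vapply(rows, function(r) length(r) == length(header), TRUE)
    if (any(!okrow)) {
      problems[[length(problems) + 1]] <- tibble::tibble(
        line = body_no[-1][!okrow], content = body[-1][!okrow]
      )
    }
    if (any(okrow)) {
      mat <- do.call(rbind, rows[okrow])
      df <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                              .name_repair = "minimal")
      names(df) <- header
      df[] <- lapply(df, function(col) {
        utils::type.convert(col, as.is = TRUE)
      })
    } else {
      df <- tibble::as_tibble(
        stats::setNames(rep(list(character(0)), length(header)), header),
        .name_repair = "minimal"
      )
    }
    blocks[[label]] <- df
  }
  new_xponent_bundle("fluorescence", metadata, blocks = blocks,
                     problems = if (length(problems)) {
                       dplyr::bind_rows(problems)
                     } else NULL)
}

import_fluorescence_dir <- function(dir) {
  idx_path <- file.path(dir, "block_index.csv")
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(idx_path) || !file.exists(meta_path)) {
    rlang::abort("not an exported fluorescence bundle directory",
                 class = "beadcal_parse_error")
  }
  idx <- utils::read.csv(idx_path, stringsAsFactors = FALSE)
  metadata <- tibble::as_tibble(
    utils::read.csv(meta_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  )
  blocks <- lapply(seq_len(nrow(idx)), function(i) {
    tibble::as_tibble(utils::read.csv(file.path(dir, idx$file[i]),
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE))
  })
  names(blocks) <- idx$label
  new_xponent_bundle("fluorescence", metadata, blocks = blocks)
}

import_bead <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    path <- list.files(path, pattern = "\\.csv(\\.gz)?$", full.names = TRUE)
  }
  if (!length(path)) {
    rlang::abort("no bead CSV files found", class = "beadcal_parse_error")
  }
  recs <- purrr::map_dfr(path, function(p) {
    if (!file.exists(p)) {
      rlang::abort(paste0("file not found: ", p), class = "beadcal_parse_error")
    }
    df <- tryCatch(
      utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE),
      error = function(e) {
        rlang::abort(paste0("cannot parse ", p, ": ", conditionMessage(e)),
                     class = "beadcal_parse_error")
      }
    )
    if (!nrow(df)) {
      rlang::abort(paste0("empty file: ", p), class = "beadcal_parse_error")
    }
    df$source <- basename(p)
    if (!"analyte" %in% names(df)) {
      df$analyte <- sub("\\.csv(\\.gz)?$", "", basename(p))
    }
    tibble::as_tibble(df)
  })
  new_xponent_bundle("bead", tibble::tibble(key = character(),
                                            value = character()),
                     bead_records = recs)
}

#' Export an xPONENT bundle to analysis-ready files
#'
#' Fluorescence bundles are written as one CSV per block plus
#' `metadata.csv` and a `block_index.csv` mapping file names back to block
#' labels; bead bundles are written as a single gzip-compressed CSV of the
#' merged bead records. [lum_import()] on the export reproduces the bundle.
#'
#' @param bundle An `xponent_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
lum_export <- function(bundle, dir) {
  stopifnot(inherits(bundle, "xponent_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (bundle$kind == "bead") {
    path <- file.path(dir, "bead_records.csv.gz")
    con <- gzfile(path, "w")
    utils::write.csv(bundle$bead_records, con, row.names = FALSE)
    close(con)
    return(invisible(path))
  }
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(bundle$metadata, meta_path, row.names = FALSE)
  labels <- names(bundle$blocks)
  files <- paste0("block-", sprintf("%02d", seq_along(labels)), "-",
                  gsub("[^A-Za-z0-9]+", "_", labels), ".csv")
  for (i in seq_along(labels)) {
    utils::write.csv(bundle$blocks[[i]], file.path(dir, files[i]),
                     row.names = FALSE)
  }
  idx_path <- file.path(dir, "block_index.csv")
  utils::write.csv(data.frame(file = files, label = labels),
                   idx_path, row.names = FALSE)
  invisible(c(meta_path, file.path(dir, files), idx_path))
}

#' Long-format wells from a fluorescence block
#'
#' Reshapes one wide block (wells in rows, analytes in columns) of a
#' fluorescence bundle into the long standard-well layout. Well positions
#' are pulled from the `Location` column (accepting both `A1` and
#' `1(1,A1)` styles) and normalized to unpadded `A1` style; columns that
#' are not well/sample identifiers are treated as analytes.
#'
#' @param bundle A fluorescence `xponent_bundle`.
#' @param block Block label to reshape (default `"Median"`).
#' @param plate_id Plate identifier to stamp on the records.
#' @param drop_cols Columns that are neither identifiers nor analytes
#'   (e.g. `"Total Events"`).
#' @return Long tibble with `plate_id`, `well`, `analyte`, `sample`,
#'   `mfi`.
#' @export
tidy_fluorescence <- function(bundle, block = "Median", plate_id = "plate_1",
                              drop_cols = "Total Events") {
  stopifnot(inherits(bundle, "xponent_bundle"),
            bundle$kind == "fluorescence")
  if (!block %in% names(bundle$blocks)) {
    rlang::abort(paste0("block '", block, "' not in bundle"),
                 class = "beadcal_input_error")
  }
  df <- bundle$blocks[[block]]
  loc_col <- intersect(c("Location", "Well"), names(df))[1]
  samp_col <- intersect(c("Sample", "sample"), names(df))[1]
  if (is.na(loc_col) || is.na(samp_col)) {
    rlang::abort("block needs Location/Well and Sample columns",
                 class = "beadcal_input_error")
  }
  well <- vapply(as.character(df[[loc_col]]), normalize_well, "")
  analyte_cols <- setdiff(names(df), c(loc_col, samp_col, drop_cols))
  long <- tidyr::pivot_longer(
    dplyr::mutate(df[analyte_cols], well = well,
                  sample = as.character(df[[samp_col]])),
    cols = dplyr::all_of(analyte_cols),
    names_to = "analyte", values_to = "mfi"
  )
  tibble::tibble(plate_id = plate_id, well = long$well,
                 analyte = long$analyte, sample = long$sample,
                 mfi = as.numeric(long$mfi))
}

normalize_well <- function(loc) {
  m <- regmatches(loc, regexpr("[A-H]0?[0-9]{1,2}", loc))
  if (!length(m)) return(NA_character_)
  paste0(substr(m, 1, 1), as.integer(substr(m, 2, nchar(m))))
}

#' Partition wells into standards, blanks, controls and tests
#'
#' Splits a long well table by matching the sample names against role
#' patterns (regular expressions). Any sample matching none of the
#' patterns is a test sample, so the partition is exhaustive; a sample
#' name matching more than one pattern is an error. Standard wells are
#' joined to their expected concentrations from a dilution map — either a
#' top concentration plus serial-dilution factor (the dilution index is
#' the integer suffix of the sample name, `Standard1` being the top), or
#' an explicit per-sample table. Raw exports never carry reliable expected
#' concentrations, so they are always supplied here.
#'
#' @param data Long tibble with at least `plate_id`, `well`, `analyte`,
#'   `sample`, `mfi`.
#' @param patterns Named list of regular expressions for roles `standard`,
#'   `blank`, `control`.
#' @param dilution Either `list(top = <conc>, factor = <f>)` or a data
#'   frame with columns `sample`, `expected_conc`. `NULL` leaves standards
#'   without concentrations (then supply them yourself).
#' @return List of tibbles `standards`, `blanks`, `tests`, `controls`.
#'   Together they contain every input row exactly once.
#' @export
data_selection <- function(data,
                           patterns = list(standard = "^Standard\\d+",
                                           blank = "^Background",
                                           control = "^Control"),
                           dilution = NULL) {
  stopifnot(is.data.frame(data), "sample" %in% names(data))
  data <- tibble::as_tibble(data)
  hits <- vapply(patterns, function(p) grepl(p, data$sample),
                 logical(nrow(data)))
  if (nrow(data) == 1) hits <- matrix(hits, nrow = 1,
                                      dimnames = list(NULL, names(patterns)))
  nhit <- rowSums(hits)
  if (any(nhit > 1)) {
    bad <- unique(data$sample[nhit > 1])
    rlang::abort(paste0("role patterns collide on samples: ",
                        paste(bad, collapse = ", ")),
                 class = "beadcal_input_error")
  }
  role <- rep("test", nrow(data))
  for (r in names(patterns)) role[hits[, r]] <- r
  standards <- data[role == "standard", ]
  if (!nrow(standards)) {
    rlang::warn("no samples matched the standard pattern",
                class = "beadcal_no_standards")
  }
  if (!is.null(dilution) && nrow(standards)) {
    if (is.data.frame(dilution)) {
      standards <- dplyr::left_join(
        standards, tibble::as_tibble(dilution)[c("sample", "expected_conc")],
        by = "sample"
      )
    } else {
      idx <- as.integer(sub("^\\D*", "", standards$sample))
      standards$expected_conc <- dilution$top / dilution$factor^(idx - 1)
    }
  }
  list(
    standards = standards,
    blanks = data[role == "blank", ],
    tests = data[role == "test", ],
    controls = data[role == "control", ]
  )
}
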