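#' Construct a publication-record corpus
#'
#' A corpus is a tibble with one row per manuscript and two list-columns:
#' `subspecialty_weights` (a named numeric vector per record, summing to 1)
#' and `authors` (a tibble per record with `raw_name`, `position`,
#' `equal_contrib`). Records are kept sorted by `(year, record_id)` so that
#' every cumulative computation downstream is order-deterministic.
#'
#' @param records A data frame (or tibble) with columns `record_id`, `year`,
#'   `journal_tier`, `randomized`, `update_index`, `citations`,
#'   `subspecialty_weights` (list of named numerics) and `authors` (list of
#'   data frames with `raw_name`, `position`, `equal_contrib`). Optional
#'   columns: `pooled_update_indices` (list of integer vectors or `NULL`) and
#'   `positive_trial` (logical passthrough, may be `NA`).
#' @param year_range Permitted calendar-year range, as a length-2 integer
#'   vector.
#'
#' @return A `trial_corpus` tibble, validated and sorted.
#' @export
#'
#' @examples
#' corp <- trial_corpus(tibble::tibble(
#'   record_id = "r1", year = 1995L, journal_tier = 1L, randomized = TRUE,
#'   update_index = 0L, citations = 120L,
#'   subspecialty_weights = list(c(breast = 1)),
#'   authors = list(tibble::tibble(
#'     raw_name = c("Alpha_Anna", "Beta_Bob"),
#'     position = 1:2, equal_contrib = FALSE
#'   ))
#' ))
#' corp
trial_corpus <- function(records, year_range = c(1900L, 2100L)) {
  records <- as_tibble(records)
  if (!"pooled_update_indices" %in% names(records)) {
    records$pooled_update_indices <- vector("list", nrow(records))
  }
  if (!"positive_trial" %in% names(records)) {
    records$positive_trial <- rep(NA, nrow(records))
  }
  records <- records[, corpus_columns(), drop = FALSE]
  records$record_id <- as.character(records$record_id)
  records$year <- as.integer(records$year)
  records$journal_tier <- as.integer(records$journal_tier)
  records$randomized <- as.logical(records$randomized)
  records$update_index <- as.integer(records$update_index)
  records$citations <- as.integer(records$citations)
  records$positive_trial <- as.logical(records$positive_trial)
  records$authors <- purrr::map(records$authors, function(a) {
    a <- as_tibble(a)
    a$raw_name <- as.character(a$raw_name)
    a$position <- as.integer(a$position)
    a$equal_contrib <- as.logical(a$equal_contrib)
    a[order(a$position), c("raw_name", "position", "equal_contrib")]
  })
  problems <- validate_corpus(records, year_range = year_range)
  if (nrow(problems) > 0) {
    abort_corpus_problems(problems)
  }
  records <- records[order(records$year, records$record_id), ]
  class(records) <- c("trial_corpus", class(tibble()))
  records
}

corpus_columns <- function() {
  c(
    "record_id", "year", "journal_tier", "randomized", "update_index",
    "pooled_update_indices", "citations", "positive_trial",
    "subspecialty_weights", "authors"
  )
}

#' Validate publication records
#'
#' Checks every corpus invariant and returns the violations as a tibble
#' rather than failing on the first one, so malformed files can be reported
#' in full.
#'
#' @param records A data frame shaped like a [trial_corpus()].
#' @param year_range Permitted year range.
#'
#' @return A tibble with columns `record_id`, `field`, `reason`; zero rows if
#'   the corpus is valid.
#' @export
validate_corpus <- function(records, year_range = c(1900L, 2100L)) {
  problems <- list()
  note <- function(id, field, reason) {
    problems[[length(problems) + 1]] <<- tibble(
      record_id = id, field = field, reason = reason
    )
  }
  if (anyDuplicated(records$record_id)) {
    dup <- unique(records$record_id[duplicated(records$record_id)])
    for (id in dup) note(id, "record_id", "duplicated record identifier")
  }
  for (i in seq_len(nrow(records))) {
    id <- as.character(records$record_id[[i]])
    if (is.na(id) || !nzchar(id)) note(id, "record_id", "missing identifier")
    yr <- records$year[[i]]
    if (is.na(yr) || yr < year_range[1] || yr > year_range[2]) {
      note(id, "year", sprintf("year %s outside [%d, %d]",
                               yr, year_range[1], year_range[2]))
    }
    if (is.na(records$update_index[[i]]) || records$update_index[[i]] < 0) {
      note(id, "update_index", "update index must be a non-negative integer")
    }
    pooled <- records$pooled_update_indices[[i]]
    if (!is.null(pooled) && length(pooled) > 0 && any(pooled < 0)) {
      note(id, "pooled_update_indices", "pooled indices must be non-negative")
    }
    if (is.na(records$citations[[i]]) || records$citations[[i]] < 0) {
      note(id, "citations", "citations must be a non-negative integer")
    }
    if (is.na(records$randomized[[i]])) {
      note(id, "randomized", "randomized flag missing")
    }
    w <- records$subspecialty_weights[[i]]
    if (length(w) == 0 || is.null(names(w)) || any(!nzchar(names(w)))) {
      note(id, "subspecialty_weights", "weights must be a named vector")
    } else if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      note(id, "subspecialty_weights",
           sprintf("weights sum to %.10g, expected 1", sum(w)))
    }
    a <- records$authors[[i]]
    if (is.null(a) || nrow(a) == 0) {
      note(id, "authors", "author list is empty")
    } else {
      if (anyDuplicated(a$position) || !setequal(a$position, seq_len(nrow(a)))) {
        note(id, "authors", "positions must be the unique sequence 1..n")
      }
      if (any(is.na(a$raw_name) | !nzchar(a$raw_name))) {
        note(id, "authors", "author names must be non-empty")
      }
    }
  }
  if (length(problems) == 0) {
    return(tibble(record_id = character(), field = character(),
                  reason = character()))
  }
  bind_rows(problems)
}

abort_corpus_problems <- function(problems) {
  msg <- paste0(
    "invalid publication records:\n",
    paste(sprintf("  - record %s, field %s: %s",
                  problems$record_id, problems$field, problems$reason),
          collapse = "\n")
  )
  abort(msg, class = "trialnet_validation_error", problems = problems)
}

#' Parse a MEDLINE-style author name
#'
#' Author names are stored as `Surname_Given` with a single underscore
#' separating the surname block (which may itself contain spaces or hyphens)
#' from the given-name block. A given block of 1--3 uppercase letters is
#' classified as initials-only; anything else is treated as a full given
#' name.
#'
#' @param raw Character vector of raw author names.
#'
#' @return A tibble with columns `raw_name`, `surname`, `given`,
#'   `initials_only`.
#' @export
#'
#' @examples
#' parse_author_name(c("Kantarjian_HM", "Rigal-Huguet_Francoise"))
parse_author_name <- function(raw) {
  raw <- as.character(raw)
  n_sep <- vapply(gregexpr("_", raw, fixed = TRUE), function(m) {
    if (length(m) == 1 && m[1] == -1) 0L else length(m)
  }, integer(1))
  parts <- strsplit(raw, "_", fixed = TRUE)
  surname <- vapply(parts, function(p) if (length(p) >= 1) p[[1]] else "",
                    character(1))
  given <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "",
                  character(1))
  bad <- is.na(raw) | !nzchar(raw) | n_sep != 1L |
    !nzchar(surname) | !nzchar(given)
  if (any(bad)) {
    abort(
      paste0("malformed author name(s): ",
             paste(sprintf("'%s'", raw[bad]), collapse = ", "),
             " (expected exactly one '_' between surname and given block)"),
      class = "trialnet_name_error", offending = raw[bad]
    )
  }
  tibble(
    raw_name = raw,
    surname = surname,
    given = given,
    initials_only = grepl("^[A-Z]{1,3}$", given)
  )
}

#' Read a corpus file
#'
#' Two dialects are supported. `"jsonl"` holds one JSON object per line with
#' a fixed key order. `"table"` is a tab-separated file with one row per
#' (record, author-slot) pair and record-level fields repeated;
#' `subspecialty_weights` are encoded as `label=weight;...` and
#' `pooled_update_indices` as `i|j|...`.
#'
#' @param path File to read.
#' @param dialect `"jsonl"` or `"table"`.
#' @param year_range Permitted year range, passed to [trial_corpus()].
#'
#' @return A validated [trial_corpus()], sorted by `(year, record_id)`.
#' @export
read_corpus <- function(path, dialect = c("jsonl", "table"),
                        year_range = c(1900L, 2100L)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("corpus file '%s' does not exist", path))
  }
  if (dialect == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    recs <- purrr::map(lines, jsonl_to_record)
    corpus_from_record_list(recs, year_range)
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      record_id = readr::col_character(),
      year = readr::col_integer(),
      journal_tier = readr::col_integer(),
      randomized = readr::col_logical(),
      update_index = readr::col_integer(),
      pooled_update_indices = readr::col_character(),
      citations = readr::col_integer(),
      positive_trial = readr::col_logical(),
      subspecialty_weights = readr::col_character(),
      author_position = readr::col_integer(),
      author_raw_name = readr::col_character(),
      author_equal_contrib = readr::col_logical()
    ), progress = FALSE)
    if (nrow(tab) == 0) return(empty_corpus())
    split_tab <- split(tab, tab$record_id)
    recs <- purrr::map(split_tab, function(rows) {
      r <- rows[1, ]
      list(
        record_id = r$record_id, year = r$year,
        journal_tier = r$journal_tier, randomized = r$randomized,
        update_index = r$update_index,
        pooled_update_indices = decode_pooled(r$pooled_update_indices),
        citations = r$citations, positive_trial = r$positive_trial,
        subspecialty_weights = decode_weights(r$subspecialty_weights),
        authors = tibble(
          raw_name = rows$author_raw_name,
          position = rows$author_position,
          equal_contrib = rows$author_equal_contrib
        )
      )
    })
    corpus_from_record_list(unname(recs), year_range)
  }
}

corpus_from_record_list <- function(recs, year_range) {
  if (length(recs) == 0) return(empty_corpus())
  records <- tibble(
    record_id = purrr::map_chr(recs, ~ as.character(.x$record_id %||% NA)),
    year = purrr::map_int(recs, ~ as.integer(.x$year %||% NA)),
    journal_tier = purrr::map_int(recs, ~ as.integer(.x$journal_tier %||% NA)),
    randomized = purrr::map_lgl(recs, ~ as.logical(.x$randomized %||% NA)),
    update_index = purrr::map_int(recs, ~ as.integer(.x$update_index %||% NA)),
    pooled_update_indices = purrr::map(recs, ~ .x$pooled_update_indices),
    citations = purrr::map_int(recs, ~ as.integer(.x$citations %||% NA)),
    positive_trial = purrr::map_lgl(
      recs, ~ as.logical(.x$positive_trial %||% NA)),
    subspecialty_weights = purrr::map(recs, "subspecialty_weights"),
    authors = purrr::map(recs, "authors")
  )
  trial_corpus(records, year_range = year_range)
}

empty_corpus <- function() {
  trial_corpus(tibble(
    record_id = character(), year = integer(), journal_tier = integer(),
    randomized = logical(), update_index = integer(),
    pooled_update_indices = list(), citations = integer(),
    positive_trial = logical(), subspecialty_weights = list(),
    authors = list()
  ))
}

jsonl_to_record <- function(line) {
  x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  w <- unlist(x$subspecialty_weights)
  authors <- tibble(
    raw_name = purrr::map_chr(x$authors, "raw_name"),
    position = purrr::map_int(x$authors, ~ as.integer(.x$position)),
    equal_contrib = purrr::map_lgl(x$authors, "equal_contrib")
  )
  pooled <- x$pooled_update_indices
  if (!is.null(pooled)) pooled <- as.integer(unlist(pooled))
  list(
    record_id = x$record_id, year = x$year, journal_tier = x$journal_tier,
    randomized = x$randomized, update_index = x$update_index,
    pooled_update_indices = pooled, citations = x$citations,
    positive_trial = x$positive_trial, subspecialty_weights = w,
    authors = authors
  )
}

decode_weights <- function(s) {
  pieces <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(pieces, "=", fixed = TRUE)
  w <- vapply(kv, function(p) as.numeric(p[[2]]), numeric(1))
  names(w) <- vapply(kv, function(p) p[[1]], character(1))
  w
}

decode_pooled <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  as.integer(strsplit(s, "|", fixed = TRUE)[[1]])
}

#' Write a corpus file
#'
#' The output is bit-stable for a fixed corpus and dialect: records are
#' written in `(year, record_id)` order, keys in a fixed order, subspecialty
#' weights with sorted labels, and numbers at full precision, so writing the
#' same corpus twice yields byte-identical files and
#' `read_corpus(write_corpus(x))` round-trips exactly.
#'
#' @param corpus A [trial_corpus()].
#' @param path Output file.
#' @param dialect `"jsonl"` or `"table"`.
#'
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, dialect = c("jsonl", "table")) {
  dialect <- match.arg(dialect)
  corpus <- corpus[order(corpus$year, corpus$record_id), ]
  if (dialect == "jsonl") {
    lines <- purrr::map_chr(seq_len(nrow(corpus)), function(i) {
      record_to_json(corpus[i, ])
    })
    writeLines(lines, path, useBytes = TRUE)
  } else {
    rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
      r <- corpus[i, ]
      a <- r$authors[[1]]
      w <- r$subspecialty_weights[[1]]
      w <- w[order(names(w))]
      tibble(
        record_id = r$record_id, year = r$year,
        journal_tier = r$journal_tier, randomized = r$randomized,
        update_index = r$update_index,
        pooled_update_indices = encode_pooled(r$pooled_update_indices[[1]]),
        citations = r$citations, positive_trial = r$positive_trial,
        subspecialty_weights = paste(
          sprintf("%s=%.17g", names(w), unname(w)), collapse = ";"),
        author_position = a$position, author_raw_name = a$raw_name,
        author_equal_contrib = a$equal_contrib
      )
    })
    tab <- if (length(rows) == 0) {
      tibble(
        record_id = character(), year = integer(), journal_tier = integer(),
        randomized = logical(), update_index = integer(),
        pooled_update_indices = character(), citations = integer(),
        positive_trial = logical(), subspecialty_weights = character(),
        author_position = integer(), author_raw_name = character(),
        author_equal_contrib = logical()
      )
    } else {
      bind_rows(rows)
    }
    readr::write_tsv(tab, path, na = "", progress = FALSE)
  }
  invisible(path)
}

encode_pooled <- function(p) {
  if (is.null(p) || length(p) == 0) return(NA_character_)
  paste(as.integer(p), collapse = "|")
}

record_to_json <- function(r) {
  w <- r$subspecialty_weights[[1]]
  w <- as.list(w[order(names(w))])
  a <- r$authors[[1]]
  authors <- purrr::map(seq_len(nrow(a)), function(j) {
    list(raw_name = a$raw_name[[j]], position = a$position[[j]],
         equal_contrib = a$equal_contrib[[j]])
  })
  pooled <- r$pooled_update_indices[[1]]
  obj <- list(
    record_id = r$record_id,
    year = r$year,
    journal_tier = r$journal_tier,
    randomized = r$randomized,
    update_index = r$update_index,
    pooled_update_indices = if (is.null(pooled)) NULL else as.list(pooled),
    citations = r$citations,
    positive_trial = r$positive_trial,
    subspecialty_weights = w,
    authors = authors
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
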