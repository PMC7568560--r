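#' Canonicalize author name forms
#'
#' Maps every raw author name form to a canonical author key. Two sources of
#' merging are applied, in order:
#'
#' 1. an explicit alias table (`raw` -> `canonical`), applied transitively
#'    until a fixed point (a cycle is a configuration error), covering
#'    misspellings, alternate surname orders, and subsumed forms;
#' 2. an automatic rule for short forms: a name whose given block is
#'    initials-only is merged into a full-name form if and only if exactly
#'    one full form among the resolved names shares its surname and has a
#'    compatible initial sequence (one initial string a prefix of the
#'    other). A short form with zero or several full-form candidates keeps
#'    its own key, since it could refer to two or more individuals.
#'
#' The result is deterministic for a fixed input and idempotent: applying
#' the mapping to its own output changes nothing.
#'
#' @param raw_names Character vector of raw name forms (duplicates allowed).
#' @param alias_table Optional data frame with columns `raw`, `canonical`.
#' @param auto_merge Apply the single-candidate initials rule (default TRUE).
#'
#' @return A tibble with columns `raw_name`, `canonical_key`, one row per
#'   distinct raw name.
#' @export
#'
#' @examples
#' canonicalize_authors(
#'   c("Benboubker_Lofti", "Benboubker_Lotfi"),
#'   alias_table = data.frame(raw = "Benboubker_Lofti",
#'                            canonical = "Benboubker_Lotfi")
#' )
canonicalize_authors <- function(raw_names, alias_table = NULL,
                                 auto_merge = TRUE) {
  raw_names <- unique(as.character(raw_names))
  key <- setNames(raw_names, raw_names)

  if (!is.null(alias_table) && nrow(alias_table) > 0) {
    amap <- setNames(as.character(alias_table$canonical),
                     as.character(alias_table$raw))
    if (anyDuplicated(names(amap))) {
      abort("alias table maps the same raw form to several canonical forms",
            class = "trialnet_alias_error")
    }
    resolve <- function(x) {
      seen <- character()
      while (x %in% names(amap)) {
        if (x %in% seen) {
          abort(sprintf("alias cycle involving '%s'", x),
                class = "trialnet_alias_error")
        }
        seen <- c(seen, x)
        x <- amap[[x]]
      }
      x
    }
    all_forms <- union(raw_names, union(names(amap), unname(amap)))
    resolved <- vapply(all_forms, resolve, character(1))
    key[] <- resolved[key]
  }

  if (auto_merge) {
    forms <- unique(unname(key))
    parsed <- parse_author_name(forms)
    full <- parsed[!parsed$initials_only, ]
    short <- parsed[parsed$initials_only, ]
    if (nrow(short) > 0 && nrow(full) > 0) {
      full$initials <- given_initials(full$given)
      merge_to <- setNames(character(0), character(0))
      for (i in seq_len(nrow(short))) {
        cand <- full[full$surname == short$surname[[i]], ]
        if (nrow(cand) == 0) next
        si <- short$given[[i]]
        compat <- vapply(cand$initials, function(fi) {
          is_prefix(si, fi) || is_prefix(fi, si)
        }, logical(1))
        cand <- cand[compat, ]
        if (length(unique(cand$raw_name)) == 1) {
          merge_to[[short$raw_name[[i]]]] <- cand$raw_name[[1]]
        }
      }
      if (length(merge_to) > 0) {
        hit <- key %in% names(merge_to)
        key[hit] <- merge_to[key[hit]]
      }
    }
  }

  tibble(raw_name = raw_names, canonical_key = unname(key[raw_names]))
}

given_initials <- function(given) {
  vapply(strsplit(given, "[ -]+"), function(p) {
    paste(toupper(substr(p, 1, 1)), collapse = "")
  }, character(1))
}

is_prefix <- function(a, b) {
  nchar(a) <= nchar(b) && substr(b, 1, nchar(a)) == a
}

#' Assign a gender category to given names
#'
#' Categories are `woman`, `man`, `unknown_initials` and `ambiguous`.
#' Initials-only names are always `unknown_initials`. For full given names
#' the sources are consulted in precedence order: an explicit override
#' table; a name-frequency table, assigning the majority gender only when
#' its ratio is strictly greater than 0.9; a dictionary table of
#' international names; otherwise `ambiguous`.
#'
#' @param given Character vector of given-name blocks (as returned by
#'   [parse_author_name()]).
#' @param initials_only Logical vector, same length as `given`.
#' @param freq_table Optional data frame `name`, `n_woman`, `n_man`
#'   (per-name counts by gender, e.g. from census data).
#' @param dictionary_table Optional data frame `name`, `gender`.
#' @param override_table Optional data frame `name`, `gender` (manual
#'   resolutions, e.g. country-dependent names).
#'
#' @return Character vector of gender categories.
#' @export
assign_gender <- function(given, initials_only,
                          freq_table = NULL, dictionary_table = NULL,
                          override_table = NULL) {
  stopifnot(length(given) == length(initials_only))
  out <- rep("ambiguous", length(given))
  out[initials_only] <- "unknown_initials"
  todo <- !initials_only

  lookup <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(rep(NA_character_, sum(todo)))
    m <- match(given[todo], as.character(tab$name))
    lab <- as.character(tab$gender)[m]
    lab[!lab %in% c("woman", "man")] <- NA_character_
    lab
  }

  res <- lookup(override_table)

  if (!is.null(freq_table) && nrow(freq_table) > 0) {
    m <- match(given[todo], as.character(freq_table$name))
    nw <- as.numeric(freq_table$n_woman)[m]
    nm <- as.numeric(freq_table$n_man)[m]
    tot <- nw + nm
    ratio <- pmax(nw, nm) / tot
    freq_lab <- ifelse(nw >= nm, "woman", "man")
    ok <- !is.na(tot) & tot > 0 & ratio > 0.9
    res[is.na(res) & ok] <- freq_lab[is.na(res) & ok]
  }

  dict <- lookup(dictionary_table)
  res[is.na(res)] <- dict[is.na(res)]
  res[is.na(res)] <- "ambiguous"
  out[todo] <- res
  out
}

#' Build the author identity table for a corpus
#'
#' Canonicalizes every raw name form in the corpus and assigns each
#' canonical author a gender category. The gender is taken from the longest
#' full given-name form merged into the key; an author whose forms are all
#' initials-only is `unknown_initials`.
#'
#' @param corpus A [trial_corpus()].
#' @inheritParams canonicalize_authors
#' @inheritParams assign_gender
#'
#' @return A list with `mapping` (tibble `raw_name`, `canonical_key`) and
#'   `identities` (tibble `canonical_key`, `gender`, `full_name_available`,
#'   `name_forms` list-column).
#' @export
author_identities <- function(corpus, alias_table = NULL, freq_table = NULL,
                              dictionary_table = NULL, override_table = NULL,
                              auto_merge = TRUE) {
  raw <- unique(unlist(purrr::map(corpus$authors, "raw_name")))
  mapping <- canonicalize_authors(raw, alias_table, auto_merge = auto_merge)
  parsed <- parse_author_name(mapping$raw_name)
  info <- mapping %>%
    mutate(given = parsed$given, initials_only = parsed$initials_only)
  identities <- info %>%
    group_by(.data$canonical_key) %>%
    summarise(
      name_forms = list(sort(unique(.data$raw_name))),
      full_name_available = any(!.data$initials_only),
      given = {
        g <- .data$given[!.data$initials_only]
        if (length(g) == 0) NA_character_ else g[which.max(nchar(g))]
      },
      .groups = "drop"
    )
  identities$gender <- assign_gender(
    ifelse(is.na(identities$given), "X", identities$given),
    initials_only = is.na(identities$given),
    freq_table = freq_table, dictionary_table = dictionary_table,
    override_table = override_table
  )
  identities <- identities %>%
    select("canonical_key", "gender", "full_name_available", "name_forms") %>%
    arrange(.data$canonical_key)
  list(mapping = mapping, identities = identities)
}
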