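# Clinical-history parsing: sentence segmentation and year-anchor resolution.
# Histories are parsed per year and per sentence; sentences without a clear
# year description are categorised as "year unknown" (NA in the years field).

# Abbreviations whose trailing period must not end a sentence.
ABBREVIATIONS <- c("e.g", "i.e", "etc", "dr", "mr", "mrs", "ms", "prof",
                   "vs", "approx", "ca", "resp", "cf", "no", "st")

#' Split a clinical history into sentences
#'
#' Conservative rule-based segmentation: sentences end at `.`, `!` or `?`
#' followed by whitespace, except after common abbreviations and inside
#' decimal numbers. The concatenation of the output equals the input modulo
#' whitespace.
#'
#' @param history_text a single character string.
#' @return character vector of sentences (no empty elements); empty input
#'   yields `character(0)`.
#' @export
split_history <- function(history_text) {
  stopifnot(is.character(history_text), length(history_text) == 1)
  text <- trimws(history_text)
  if (!nzchar(text)) return(character(0))
  # protect decimals: 3.5 -> 3<DOT>5
  prot <- gsub("(\\d)\\.(\\d)", "\\1\uE000\\2", text)
  # protect abbreviation periods (case-insensitive), incl. multi-dot e.g./i.e.
  for (ab in ABBREVIATIONS) {
    pat <- paste0("(?i)\\b", gsub("\\.", "\\\\.", ab), "\\.")
    repl_ab <- gsub(".", "\uE000", ab, fixed = TRUE)
    # rebuild the abbreviation with protected internal dots + protected final dot
    prot <- gsub(pat, paste0(gsub("\\.", "\uE000", ab), "\uE000"), prot,
                 perl = TRUE)
  }
  parts <- strsplit(prot, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- gsub("\uE000", ".", parts, fixed = TRUE)
  parts <- parts[nzchar(trimws(parts))]
  trimws(parts)
}

#' Resolve the calendar year(s) a sentence refers to
#'
#' Handles literal 4-digit years, year ranges (`2005-2007`, expanded to every
#' year), relative expressions (`last N years`, `last N months`, `at birth`)
#' and back-references (`in comparison to 2003`, which do not anchor the
#' sentence). Years are bounded by birth and death year; a year beyond the
#' death year raises a warning and is dropped. A sentence without any usable
#' anchor returns `NA_integer_` ("year unknown").
#'
#' Relative expressions resolve against `preceding_year` when available, else
#' `death_year`; `last N years` spans the N+1 calendar years from anchor-N to
#' the anchor; sub-year expressions (`last N months`) map to the anchor year.
#' `at birth` maps to `death_year - age_at_death`.
#'
#' @param sentence one sentence string.
#' @param death_year donor's year of death (anchor for relative expressions).
#' @param age_at_death donor's age at death in years (anchor for `at birth`).
#' @param preceding_year optional year of the enclosing history section.
#' @return sorted integer vector of years, or `NA_integer_` for year unknown.
#' @export
resolve_years <- function(sentence, death_year = NULL, age_at_death = NULL,
                          preceding_year = NULL) {
  stopifnot(is.character(sentence), length(sentence) == 1)
  anchor <- preceding_year %||% death_year
  birth_year <- if (!is.null(death_year) && !is.null(age_at_death)) {
    death_year - age_at_death
  } else NULL

  years <- integer(0)
  s <- sentence

  # back-references: strip the referenced year so it does not anchor
  s <- gsub("(?i)(in comparison (to|with)|compared (to|with)|than in)\\s+((19|20)\\d{2})",
            "\\1 <ref>", s, perl = TRUE)

  # ranges: 2005-2007 / 2005--2007 / en dash / "2005 to 2007"
  range_pat <- "((19|20)\\d{2})\\s*(\u2013|\u2014|-{1,2}|to|until)\\s*((19|20)\\d{2})"
  m <- gregexpr(range_pat, s, perl = TRUE)[[1]]
  if (m[1] != -1) {
    for (txt in regmatches(s, m)[[1]]) {
      ys <- as.integer(regmatches(txt, gregexpr("(19|20)\\d{2}", txt))[[1]])
      if (ys[2] >= ys[1]) years <- c(years, seq(ys[1], ys[2]))
    }
    s <- gsub(range_pat, " ", s, perl = TRUE)
  }

  # literal years
  lit <- regmatches(s, gregexpr("\\b(19|20)\\d{2}\\b", s))[[1]]
  years <- c(years, as.integer(lit))

  # relative: last N years / months
  rel <- regmatches(s, regexec("(?i)\\blast\\s+(\\d+)\\s+(years?|months?)", s,
                               perl = TRUE))[[1]]
  if (length(rel) && !is.null(anchor)) {
    n <- as.integer(rel[2])
    if (grepl("year", tolower(rel[3]))) {
      years <- c(years, seq(anchor - n, anchor))
    } else {
      years <- c(years, anchor) # sub-year expressions: anchor year only
    }
  }

  # at birth
  if (grepl("(?i)\\bat birth\\b", s, perl = TRUE) && !is.null(birth_year)) {
    years <- c(years, birth_year)
  }

  years <- sort(unique(as.integer(years)))
  if (!is.null(death_year) && any(years > death_year)) {
    warning(sprintf("year(s) beyond death year %d in: %s", death_year,
                    substr(sentence, 1, 60)), call. = FALSE)
    years <- years[years <= death_year]
  }
  if (!is.null(birth_year)) years <- years[years >= birth_year]
  if (!length(years)) return(NA_integer_)
  years
}

#' Parse a donor's clinical history into year-anchored sentences
#'
#' Accepts the fixture dialect with optional `YEAR:` section headers (a line
#' `2005:` sets the section year for following sentences until the next
#' header). Each sentence is year-resolved with [resolve_years()].
#'
#' @param donor_id opaque donor key.
#' @param history_text full clinical-history text.
#' @param death_year,age_at_death donor anchors for relative expressions.
#' @return a `data.frame` with one row per sentence: `donor_id`, `text`,
#'   `years` (semicolon-joined, or `"UNKNOWN"`), `source_order`.
#' @export
parse_history <- function(donor_id, history_text, death_year = NULL,
                          age_at_death = NULL) {
  lines <- strsplit(history_text, "\n", fixed = TRUE)[[1]]
  section_year <- NULL
  out <- list()
  order <- 0L
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line)) next
    hdr <- regmatches(line, regexec("^((19|20)\\d{2}):\\s*(.*)$", line))[[1]]
    if (length(hdr)) {
      section_year <- as.integer(hdr[2])
      line <- hdr[4]
      if (!nzchar(line)) next
    }
    for (sent in split_history(line)) {
      order <- order + 1L
      ys <- resolve_years(sent, death_year = death_year,
                          age_at_death = age_at_death,
                          preceding_year = section_year)
      # a bare section header year counts as this sentence's year when the
      # sentence itself has no anchor
      if (all(is.na(ys)) && !is.null(section_year)) ys <- section_year
      out[[order]] <- data.frame(
        donor_id = donor_id, text = sent,
        years = if (all(is.na(ys))) "UNKNOWN" else join_set(ys),
        source_order = order, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(donor_id = character(), text = character(),
                      years = character(), source_order = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
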