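# Scientific-name parsing and normalisation.
#
# Checklist names carry identification hedges (qualifiers) that make a name a
# distinct reported taxon: "Nereis cf. zonata" is not the same entry as
# "Nereis zonata", and "Chaetopterus variopedatus complex" is not
# "Chaetopterus variopedatus". Parsing separates the nomenclatural parts
# (genus, epithet, infraspecific epithet, subgenus), the qualifier, the
# authority citation and any trailing remark ("sensu ..." annotations on
# provisional names). Matching keys are derived from the parts; verbatim
# strings are preserved everywhere else.

QUALIFIERS <- c("none", "cf.", "aff.", "s. lat.", "sp.", "complex")
QUALIFIER_KEY <- c("cf." = "cf", "aff." = "aff", "s. lat." = "slat",
                   "sp." = "sp", "complex" = "complex")

#' Parse a scientific name into its parts
#'
#' Splits a verbatim checklist name into genus, specific and infraspecific
#' epithets, an optional subgenus, an identification qualifier (`cf.`,
#' `aff.`, `s. lat.`, `sp.`, `complex`), the authority citation and any
#' trailing free-text remark. Parsing is deterministic; a string without a
#' leading capitalised word is rejected rather than guessed at.
#'
#' @param raw a single verbatim scientific name, e.g.
#'   `"Tubulanus sexlineatus (Coe, 1904)"`.
#' @return an object of class `parsed_name`: a list with elements `genus`,
#'   `subgenus`, `epithet`, `infraspecificEpithet`, `qualifier`,
#'   `designator` (the "A" in "Myxicola sp. A"), `authority`, `remark` and
#'   `verbatim`.
#' @export
#' @examples
#' parse_scientific_name("Tubulanus sexlineatus (Coe, 1904)")
#' parse_scientific_name("Nereis cf zonata")
#' parse_scientific_name("Barentsia sp.")
parse_scientific_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- squish(raw)
  if (!nzchar(s)) stop("empty scientific name", call. = FALSE)

  verbatim <- s
  authority <- ""
  remark <- ""
  subgenus <- ""
  designator <- ""

  # Subgenus: a single parenthesised capitalised word directly after the
  # genus, e.g. "Golfingia (Golfingia) vulgaris".
  m <- regmatches(s, regexec("^([A-Z][A-Za-z-]+) \\(([A-Z][A-Za-z-]+)\\) ", s))[[1]]
  if (length(m)) {
    subgenus <- m[3]
    s <- squish(sub("^([A-Z][A-Za-z-]+) \\(([A-Z][A-Za-z-]+)\\) ", "\\1 ", s))
  }

  # Parenthesised authority containing a year, e.g. "(Coe, 1904)".
  m <- regmatches(s, regexec("\\(([^()]*[0-9]{4}[^()]*)\\)", s))[[1]]
  if (length(m)) {
    authority <- paste0("(", m[2], ")")
    s <- squish(sub("\\(([^()]*[0-9]{4}[^()]*)\\)", " ", s))
  } else {
    # Unparenthesised trailing authority "Author[, Author & Author], 1904".
    m <- regmatches(s, regexec("\\s((?:van |de |[A-Z])[A-Za-zÀ-ſ.'\\-]*(?:[^,]*?)?(?:,[^,0-9]+)*,\\s*[0-9]{4}[a-z]?)$", s))[[1]]
    if (length(m)) {
      authority <- m[2]
      s <- squish(substr(s, 1L, nchar(s) - nchar(m[1])))
    }
  }

  # Trailing remark after a comma ("..., sensu Leslie Harris, provisional
  # name"); kept verbatim, excluded from identity.
  m <- regmatches(s, regexec(",\\s*(.+)$", s))[[1]]
  if (length(m)) {
    remark <- m[2]
    s <- squish(sub(",\\s*.+$", "", s))
  }

  tokens <- strsplit(s, " ", fixed = TRUE)[[1]]
  if (!length(tokens) || !grepl("^[A-ZÀ-Þ]", tokens[1]))
    stop("unparseable scientific name (no leading capitalised word): ",
         sQuote(raw), call. = FALSE)

  genus <- tokens[1]
  tokens <- tokens[-1]

  qualifier <- "none"
  take_qualifier <- function(q) {
    if (qualifier != "none" && qualifier != q)
      stop("conflicting qualifiers in ", sQuote(raw), call. = FALSE)
    qualifier <<- q
  }

  rest <- character(0)
  i <- 1L
  while (i <= length(tokens)) {
    tok <- tokens[i]
    low <- tolower(tok)
    if (low %in% c("cf", "cf.")) {
      take_qualifier("cf.")
    } else if (low %in% c("aff", "aff.")) {
      take_qualifier("aff.")
    } else if (low %in% c("sp", "sp.")) {
      take_qualifier("sp.")
      # "sp. A" style provisional designator
      if (i < length(tokens) && grepl("^[A-Z0-9][A-Za-z0-9]?$", tokens[i + 1L])) {
        designator <- tokens[i + 1L]
        i <- i + 1L
      }
    } else if (low %in% c("s.", "s") && i < length(tokens) &&
               tolower(tokens[i + 1L]) %in% c("lat.", "lat")) {
      take_qualifier("s. lat.")
      i <- i + 1L
    } else if (low == "complex") {
      take_qualifier("complex")
    } else {
      rest <- c(rest, tok)
    }
    i <- i + 1L
  }

  if (length(rest) > 2L)
    stop("too many name tokens in ", sQuote(raw),
         " (after qualifier/authority extraction): ",
         paste(rest, collapse = " "), call. = FALSE)
  epithet <- if (length(rest) >= 1L) tolower(rest[1]) else ""
  infra <- if (length(rest) == 2L) tolower(rest[2]) else ""

  structure(
    list(genus = genus, subgenus = subgenus, epithet = epithet,
         infraspecificEpithet = infra, qualifier = qualifier,
         designator = designator, authority = authority, remark = remark,
         verbatim = verbatim),
    class = "parsed_name")
}

#' Render a parsed name back to a string
#'
#' The inverse of [parse_scientific_name()] up to whitespace and qualifier
#' spelling normalisation: parsing the rendered string yields an identical
#' `parsed_name`.
#'
#' @param p a `parsed_name`.
#' @return a single character string.
#' @export
render_scientific_name <- function(p) {
  stopifnot(inherits(p, "parsed_name"))
  parts <- p$genus
  if (nzchar(p$subgenus)) parts <- c(parts, paste0("(", p$subgenus, ")"))
  if (p$qualifier %in% c("cf.", "aff.")) parts <- c(parts, p$qualifier)
  if (p$qualifier == "sp.") {
    parts <- c(parts, "sp.")
    if (nzchar(p$designator)) parts <- c(parts, p$designator)
  }
  if (nzchar(p$epithet)) parts <- c(parts, p$epithet)
  if (nzchar(p$infraspecificEpithet)) parts <- c(parts, p$infraspecificEpithet)
  if (p$qualifier == "s. lat.") parts <- c(parts, "s. lat.")
  if (p$qualifier == "complex") parts <- c(parts, "complex")
  if (nzchar(p$authority)) parts <- c(parts, p$authority)
  out <- paste(parts, collapse = " ")
  if (nzchar(p$remark)) out <- paste0(out, ", ", p$remark)
  out
}

#' @export
print.parsed_name <- function(x, ...) {
  cat("<parsed_name> ", render_scientific_name(x), "\n", sep = "")
  cat("  key: ", canonical_key(x), "\n", sep = "")
  invisible(x)
}

#' Canonical matching key of a name
#'
#' The deterministic, normalised key used for all grouping and matching:
#' lowercase, diacritics stripped, whitespace collapsed, authority and
#' subgenus and remarks omitted. Identification qualifiers are retained as a
#' `?`-suffix token because a qualified name is a distinct taxon
#' (`"nereis zonata?cf"` differs from `"nereis zonata"`); provisional
#' designators are appended to the suffix (`"myxicola?sp-a"`).
#'
#' @param x a `parsed_name`, or a character vector of verbatim names which
#'   are parsed first.
#' @return character vector of keys.
#' @export
#' @examples
#' canonical_key("Zelentia punicea Korshunova et al., 2018")
#' canonical_key("Nereis cf zonata")
canonical_key <- function(x) {
  if (is.character(x)) return(vapply(x, function(s)
    canonical_key(parse_scientific_name(s)), character(1), USE.NAMES = FALSE))
  stopifnot(inherits(x, "parsed_name"))
  base <- tolower(strip_diacritics(squish(paste(
    x$genus, x$epithet, x$infraspecificEpithet))))
  if (x$qualifier != "none") {
    suffix <- QUALIFIER_KEY[[x$qualifier]]
    if (nzchar(x$designator))
      suffix <- paste0(suffix, "-", tolower(strip_diacritics(x$designator)))
    base <- paste0(base, "?", suffix)
  }
  base
}

#' Validate a claimed authority against the backbone's authority
#'
#' Authorities are validated, never matched on. `exact` means byte-identical;
#' `normalizedMatch` means identical once parentheses, diacritics and all
#' whitespace differences are removed (so `"Coe, 1904"` matches
#' `"(Coe, 1904)"`); `missing` means the claimed authority is empty.
#'
#' @param claimed authority string as supplied by an expert or source.
#' @param backbone_authority the authority recorded in the taxonomic
#'   backbone for the same taxon.
#' @return one of `"exact"`, `"normalizedMatch"`, `"mismatch"`, `"missing"`.
#' @export
match_authority <- function(claimed, backbone_authority) {
  stopifnot(length(claimed) == 1L, length(backbone_authority) == 1L)
  if (is.na(claimed) || !nzchar(trimws(claimed))) return("missing")
  if (identical(claimed, backbone_authority)) return("exact")
  norm <- function(x) {
    x <- strip_diacritics(x)
    x <- gsub("[()]", "", x)
    gsub("[[:space:]]+", "", x)
  }
  if (identical(norm(claimed), norm(backbone_authority))) return("normalizedMatch")
  "mismatch"
}
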