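#' Database label registry
#'
#' Bibliographic databases appear in exports under many source strings
#' ("Embase.com", "MEDLINE in Ovid", "PubMed publisher \[sb\]", ...). A
#' registry maps each source string (alias) to one canonical short token.
#' The alias map is many-to-one and case-insensitive. Merges such as folding
#' the PubMed "as supplied by publisher" subset into MEDLINE are expressed
#' purely through aliasing, never through special-cased code.
#'
#' @param aliases Named list: canonical token -> character vector of aliases.
#'   The canonical token itself is always accepted as its own alias.
#' @return A `db_registry` object (named list of lower-cased alias vectors).
#' @examples
#' reg <- db_registry(list(EMBASE = c("embase", "embase.com")))
#' canonicalize_database("Embase.com", reg)
#' @export
db_registry <- function(aliases) {
  if (length(aliases) == 0 || is.null(names(aliases)) || any(names(aliases) == "")) {
    sr_abort("validation", "A registry needs at least one named canonical database.")
  }
  canon <- names(aliases)
  if (anyDuplicated(canon)) {
    sr_abort("validation", "Canonical database names must be unique within a registry.")
  }
  out <- lapply(seq_along(aliases), function(i) {
    unique(norm_label(c(canon[[i]], as.character(aliases[[i]]))))
  })
  names(out) <- canon
  all_alias <- unlist(out, use.names = FALSE)
  if (anyDuplicated(all_alias)) {
    dup <- unique(all_alias[duplicated(all_alias)])
    sr_abort("validation",
             sprintf("Alias map must be many-to-one; duplicated alias(es): %s",
                     paste(dup, collapse = ", ")))
  }
  structure(out, class = "db_registry")
}

# lower-case, trim, collapse internal whitespace
norm_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Default database registry
#'
#' Canonical tokens for the databases commonly searched for biomedical
#' systematic reviews, with the aliases seen in reference-manager exports.
#' Ovid MEDLINE and the PubMed "as supplied by publisher" subset both map to
#' `MEDLINE`, reflecting that the publisher subset only supplements MEDLINE
#' with not-yet-indexed records.
#'
#' @return A `db_registry`.
#' @export
default_registry <- function() {
  db_registry(list(
    EMBASE = c("embase", "embase.com", "em", "embase classic"),
    MEDLINE = c("medline", "ml", "medline in ovid", "ovid medline",
                "medline (ovid)", "pubmed", "pubmed publisher [sb]",
                "pubmed (as supplied by publisher)", "publisher [sb]",
                "pubmed publisher subset"),
    COCHRANE_CENTRAL = c("central", "cochrane central", "cochrane",
                         "cochrane central register of controlled trials",
                         "central (wiley)"),
    WOS = c("wos", "web of science", "web of science core collection",
            "isi web of science", "web of knowledge"),
    GS = c("gs", "google scholar"),
    CINAHL = c("cinahl", "cinahl (ebscohost)", "cinahl ebsco"),
    PSYCINFO = c("psycinfo", "psycinfo (ovid)", "psychinfo"),
    SCOPUS = c("scopus", "scopus (elsevier)"),
    SPORTDISCUS = c("sportdiscus", "sportdiscus (ebscohost)")
  ))
}

#' Map a raw database label to its canonical token
#'
#' Matching is case-insensitive and whitespace-trimmed. Unknown labels raise
#' an error rather than silently minting new databases, so typos in corpus
#' files surface at load time.
#'
#' @param raw_label Character vector of source strings.
#' @param registry A [db_registry()]; defaults to [default_registry()].
#' @return Character vector of canonical tokens, same length as `raw_label`.
#' @examples
#' canonicalize_database("PubMed publisher [sb]")
#' canonicalize_database(c("embase.com", "EMBASE"))
#' @export
canonicalize_database <- function(raw_label, registry = default_registry()) {
  stopifnot(inherits(registry, "db_registry"))
  key <- norm_label(raw_label)
  lut <- alias_lookup(registry)
  hit <- lut[key]
  if (anyNA(hit)) {
    bad <- unique(raw_label[is.na(hit)])
    sr_abort("unknown_database",
             sprintf("Unknown database label(s): %s. Add them to the registry aliases.",
                     paste(sQuote(bad), collapse = ", ")))
  }
  unname(hit)
}

alias_lookup <- function(registry) {
  n <- lengths(registry)
  setNames(rep(names(registry), n), unlist(registry, use.names = FALSE))
}

#' @export
print.db_registry <- function(x, ...) {
  cat("<db_registry> ", length(x), " canonical databases\n", sep = "")
  for (nm in names(x)) cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
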