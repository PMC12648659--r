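#' Load a CAS-indexed solvent HSP database from CSV
#'
#' The file is UTF-8, comma-separated, with a header row containing at least
#' \code{cas,name,synonyms,smiles,dD,dP,dH}. Synonyms are packed into one
#' field with \code{";"} separators. Extra columns (boiling point and the
#' like) are carried through untouched and never interpreted.
#'
#' Validation applied on load: unique CAS values, non-empty names, unambiguous
#' name/synonym resolution, finite non-negative HSPs. CAS strings must match
#' the digits-digits-digit registry pattern; the CAS check digit is verified
#' too but a mismatch is only a warning (databases in the wild contain
#' transcription slips).
#'
#' @param path CSV file path
#' @return an object of class \code{"solvent_db"}: the record data frame plus
#'   lookup indices by CAS and by lower-cased name/synonym
#' @seealso [get_solvent()], [validate_solvent_db()], [default_solvent_db()]
#' @export
load_solvent_db <- function(path) {
  if (!file.exists(path)) stop_io("solvent database file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("cas", "name", "synonyms", "smiles", "dD", "dP", "dH")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_schema("solvent database is missing required column(s): ",
                paste(missing, collapse = ", "))
  for (col in c("dD", "dP", "dH")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[col]])) | is.na(v))
    if (length(bad))
      stop_schema("unparseable numeric in column '", col, "' at line ",
                  paste(bad + 1L, collapse = ", "))  # +1 for the header row
    df[[col]] <- v
  }
  db <- new_solvent_db(df)
  issues <- validate_solvent_db(db)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop_validation("solvent database failed validation:\n  ",
                    paste(errs$message, collapse = "\n  "))
  for (w in issues$message[issues$severity == "warning"]) warning(w, call. = FALSE)
  db
}

new_solvent_db <- function(df) {
  df$name <- trimws(df$name)
  df$cas <- trimws(df$cas)
  syn <- strsplit(as.character(ifelse(is.na(df$synonyms), "", df$synonyms)),
                  ";", fixed = TRUE)
  syn <- lapply(syn, function(s) trimws(s[nzchar(trimws(s))]))
  keys <- mapply(function(n, s) unique(tolower(c(n, s))), df$name, syn,
                 SIMPLIFY = FALSE)
  name_index <- data.frame(
    key = unlist(keys, use.names = FALSE),
    row = rep.int(seq_len(nrow(df)), lengths(keys)),
    stringsAsFactors = FALSE
  )
  structure(list(records = df, synonyms = syn, name_index = name_index),
            class = "solvent_db")
}

#' @export
print.solvent_db <- function(x, ...) {
  cat(sprintf("<solvent_db> %d solvent(s), indexed by CAS, name and synonym\n",
              nrow(x$records)))
  invisible(x)
}

#' @export
length.solvent_db <- function(x) nrow(x$records)

#' Validate a solvent database
#'
#' Re-checks all database invariants and returns a data frame of issues with
#' columns \code{severity} (\code{"error"} or \code{"warning"}),
#' \code{record} (1-based record number, NA for cross-record issues) and
#' \code{message}. An empty data frame means the database is clean.
#'
#' @param db a \code{solvent_db}
#' @return data frame of issues (zero rows if none)
#' @export
validate_solvent_db <- function(db) {
  df <- db$records
  issues <- list()
  add <- function(severity, record, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, record = record, message = message,
      stringsAsFactors = FALSE)

  dup <- unique(df$cas[duplicated(df$cas)])
  for (d in dup)
    add("error", NA_integer_, paste0("duplicate CAS number: ", d))
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$name[i]))
      add("error", i, paste0("record ", i, ": empty name"))
    h <- c(df$dD[i], df$dP[i], df$dH[i])
    if (!all(is.finite(h)) || any(h < 0))
      add("error", i, paste0("record ", i, " (", df$name[i],
                             "): HSPs must be finite and non-negative"))
    if (!grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", df$cas[i]))
      add("warning", i, paste0("record ", i, " (", df$name[i],
                               "): malformed CAS number '", df$cas[i], "'"))
    else if (!cas_checksum_ok(df$cas[i]))
      add("warning", i, paste0("record ", i, " (", df$name[i],
                               "): CAS check digit mismatch in '", df$cas[i], "'"))
  }
  # a key is ambiguous only when it maps to two *different* records
  tab <- unique(db$name_index)
  amb <- unique(tab$key[duplicated(tab$key)])
  for (k in amb)
    add("error", NA_integer_,
        paste0("name/synonym '", k, "' resolves to more than one record"))
  if (!length(issues))
    return(data.frame(severity = character(), record = integer(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

# CAS check digit: sum of digits weighted by position from the right
# (excluding the check digit itself), modulo 10.
cas_checksum_ok <- function(cas) {
  digits <- as.integer(strsplit(gsub("-", "", cas), "")[[1]])
  n <- length(digits)
  check <- digits[n]
  body <- digits[-n]
  sum(body * rev(seq_along(body))) %% 10 == check
}

#' Look up a solvent by CAS number, name or synonym
#'
#' Name and synonym matching is case-insensitive; CAS matching is exact.
#'
#' @param db a \code{solvent_db}
#' @param key CAS registry number, canonical name or synonym
#' @return a one-row list with fields \code{cas}, \code{name},
#'   \code{synonyms} (character vector), \code{smiles} and \code{hsp}
#'   (an [hsp()] vector)
#' @examples
#' db <- default_solvent_db()
#' get_solvent(db, "THF")$hsp
#' @export
get_solvent <- function(db, key) {
  key <- trimws(as.character(key)[1])
  i <- which(db$records$cas == key)
  if (!length(i)) {
    hit <- db$name_index$row[db$name_index$key == tolower(key)]
    i <- unique(hit)
  }
  if (!length(i))
    stop_not_found("no solvent matching '", key, "' in database")
  if (length(i) > 1L)
    stop_ambiguous("'", key, "' is ambiguous; candidates: ",
                   paste(db$records$name[i], collapse = ", "))
  rec <- db$records[i, , drop = FALSE]
  list(cas = rec$cas, name = rec$name, synonyms = db$synonyms[[i]],
       smiles = rec$smiles, hsp = hsp(rec$dD, rec$dP, rec$dH))
}

#' Write a solvent database back to CSV
#'
#' Numeric fields are serialized at full precision (17 significant digits) so
#' that \code{load_solvent_db(write_solvent_db(db, f))} round-trips exactly.
#'
#' @param db a \code{solvent_db}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_solvent_db <- function(db, path) {
  df <- db$records
  out <- df
  for (col in c("dD", "dP", "dH")) out[[col]] <- sprintf("%.17g", df[[col]])
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8"),
    error = function(e) stop_io("cannot write solvent database: ",
                                conditionMessage(e)))
  invisible(path)
}

#' The bundled solvent database
#'
#' Fourteen common laboratory solvents spanning the practical Hansen space
#' (dD roughly 14-19, dP 0-18, dH 0-42 MPa^(1/2)), with CAS numbers, common
#' synonyms and SMILES. This is the panel used throughout the package's
#' examples and is deliberately small; users with wider screens should load
#' their own file via [load_solvent_db()].
#'
#' @return a \code{solvent_db}
#' @export
default_solvent_db <- function() {
  suppressWarnings(
    load_solvent_db(system.file("extdata", "solvents.csv", package = "hsploc",
                                mustWork = TRUE)))
}
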