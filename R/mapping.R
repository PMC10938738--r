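#' Load an ATC-to-disease-category mapping
#'
#' Reads a delimited mapping file with columns `atc_prefix`, `category_id`
#' and `category_name`, and validates it: prefixes must be syntactically
#' valid ATC truncations, and no full 7-character ATC code may resolve to
#' two different categories. A code is resolved by *longest-prefix* matching,
#' so a chemical-substance entry (e.g. `N05AN`) can carve a specific drug
#' group out of a broader therapeutic entry (e.g. `N05A`) without ambiguity.
#'
#' @param path Path to a delimited text file. Defaults to the mapping shipped
#'   with the package (see [default_mapping()]).
#' @return A `data.table` with columns `atc_prefix`, `category_id`,
#'   `category_name`, one row per prefix entry.
#' @details The shipped default mapping is a reconstruction of the 46-category
#'   medication-based Rx-Risk Comorbidity Index from its published category
#'   list; its exact prefixes are plausible rather than authoritative, and
#'   users with access to a validated national mapping should supply their
#'   own file in the same format.
#' @export
load_mapping <- function(path = default_mapping_path()) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  map <- fread(path, colClasses = "character")
  required <- c("atc_prefix", "category_id", "category_name")
  if (!all(required %in% names(map))) {
    stop("mapping file must have columns: ", paste(required, collapse = ", "))
  }
  map <- map[, ..required]
  if (nrow(map) == 0L) stop("mapping file is empty: ", path)
  bad <- map$atc_prefix[!grepl("^[A-V]([0-9]{2}([A-Z]{1,2}([0-9]{1,2})?)?)?$",
                               map$atc_prefix)]
  if (length(bad)) {
    stop("invalid ATC prefix(es) in mapping: ", paste(unique(bad), collapse = ", "))
  }
  dup <- map[, .N, by = atc_prefix][N > 1L]$atc_prefix
  if (length(dup)) {
    ex <- example_code_for_prefix(dup[1L])
    stop("ambiguous mapping: prefix ", dup[1L], " appears more than once, ",
         "so code ", ex, " would resolve to two categories")
  }
  setkey(map, atc_prefix)
  map[]
}

#' Path to the packaged default category mapping
#' @return File path of the reconstruction of the 46-category index mapping.
#' @export
default_mapping_path <- function() {
  system.file("extdata", "rxrisk_mapping_default.csv", package = "rxrisk",
              mustWork = TRUE)
}

#' The packaged default ATC-to-category mapping
#' @return A validated mapping `data.table` (46 disease categories).
#' @seealso [load_mapping()]
#' @export
default_mapping <- function() load_mapping(default_mapping_path())

## Pad a prefix out to a syntactically complete 7-character ATC code.
example_code_for_prefix <- function(prefix) {
  template <- "A01AA01"
  paste0(prefix, substr(template, nchar(prefix) + 1L, 7L))
}

#' Resolve full ATC codes to disease categories by longest-prefix match
#'
#' @param codes Character vector of 7-character ATC codes.
#' @param mapping Mapping from [load_mapping()].
#' @return Character vector of `category_id`s, `NA` where no prefix matches
#'   (a non-index medication).
#' @export
match_atc <- function(codes, mapping) {
  lookup <- setNames(mapping$category_id, mapping$atc_prefix)
  out <- rep(NA_character_, length(codes))
  for (len in 7:1) {
    todo <- is.na(out)
    if (!any(todo)) break
    hit <- lookup[substr(codes[todo], 1L, len)]
    out[todo] <- unname(hit)
  }
  out
}

#' Assign dispensings to disease categories per person and calendar year
#'
#' Implements the set semantics of the index: a person-year's category set
#' contains a category if at least one dispensing that year maps to it, no
#' matter how many fills. Codes matching no prefix are counted as non-index
#' fills; the person-year still counts as observed (the person visited a
#' pharmacy), which matters downstream when distinguishing a score of zero
#' from a missing score.
#'
#' @param dispensings `data.table` with columns `person_id`, `atc`, `year`,
#'   `month`.
#' @param mapping Mapping from [load_mapping()].
#' @return A list of class `rxrisk_categories` with elements
#'   \describe{
#'     \item{categories}{`data.table` (`person_id`, `year`, `category_id`),
#'       one row per distinct person-year-category.}
#'     \item{person_years}{`data.table` (`person_id`, `year`, `n_fills`,
#'       `n_index`, `n_nonindex`), one row per observed person-year.}
#'     \item{n_malformed}{count of dispensing rows skipped for malformed
#'       ATC codes.}
#'   }
#' @export
assign_categories <- function(dispensings, mapping) {
  d <- as.data.table(dispensings)
  required <- c("person_id", "atc", "year", "month")
  if (!all(required %in% names(d))) {
    stop("dispensings must have columns: ", paste(required, collapse = ", "))
  }
  ok <- grepl("^[A-V][0-9]{2}[A-Z]{2}[0-9]{2}$", d$atc)
  n_malformed <- sum(!ok)
  if (n_malformed > 0L) {
    warning(n_malformed, " dispensing row(s) with malformed ATC codes skipped")
    d <- d[ok]
  }
  if (nrow(d) == 0L) {
    return(structure(list(
      categories = data.table(person_id = integer(), year = integer(),
                              category_id = character()),
      person_years = data.table(person_id = integer(), year = integer(),
                                n_fills = integer(), n_index = integer(),
                                n_nonindex = integer()),
      n_malformed = n_malformed), class = "rxrisk_categories"))
  }
  code_map <- data.table(atc = unique(d$atc))
  code_map[, category_id := match_atc(atc, mapping)]
  d <- code_map[d, on = "atc"]
  person_years <- d[, .(n_fills = .N,
                        n_index = sum(!is.na(category_id)),
                        n_nonindex = sum(is.na(category_id))),
                    by = .(person_id, year)]
  categories <- unique(d[!is.na(category_id),
                         .(person_id, year, category_id)])
  setkey(categories, person_id, year, category_id)
  setkey(person_years, person_id, year)
  structure(list(categories = categories, person_years = person_years,
                 n_malformed = n_malformed),
            class = "rxrisk_categories")
}

#' @export
print.rxrisk_categories <- function(x, ...) {
  cat("rxrisk category assignment:",
      nrow(x$person_years), "observed person-years,",
      nrow(x$categories), "person-year-category rows,",
      x$n_malformed, "malformed codes skipped\n")
  invisible(x)
}
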