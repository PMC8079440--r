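#' The 62-region Desikan-Killiany-Tourville cortical region set
#'
#' Returns the ordered set of 62 cortical regions (31 gyral labels per
#' hemisphere) of the Desikan-Killiany-Tourville (DKT) parcellation protocol,
#' the unit at which all thickness tables in this package are indexed.
#' Region codes are the conventional short abbreviations prefixed by
#' hemisphere (`lh_` / `rh_`), left hemisphere first.
#'
#' @return A data.frame with 62 rows and columns `code` (e.g. `"lh_ENT"`),
#'   `abbrev` (e.g. `"ENT"`), `name` (full label), and `hemisphere`
#'   (`"left"` or `"right"`).
#' @examples
#' r <- dkt_regions()
#' table(r$hemisphere)
#' @export
dkt_regions <- function() {
  abbrev <- c(
    "cACC", "cMFG", "CUN", "ENT", "FUS", "IPL", "ITG", "iCC", "LOG",
    "LOF", "LING", "MOF", "MTG", "PARH", "paraC", "pOPER", "pORB",
    "pTRI", "periCAL", "postC", "PCC", "preC", "PCUN", "rACC", "rMFG",
    "SFG", "SPL", "STG", "SMAR", "TT", "INS"
  )
  name <- c(
    "caudal anterior cingulate", "caudal middle frontal", "cuneus",
    "entorhinal", "fusiform", "inferior parietal", "inferior temporal",
    "isthmus cingulate", "lateral occipital", "lateral orbitofrontal",
    "lingual", "medial orbitofrontal", "middle temporal",
    "parahippocampal", "paracentral", "pars opercularis", "pars orbitalis",
    "pars triangularis", "pericalcarine", "postcentral",
    "posterior cingulate", "precentral", "precuneus",
    "rostral anterior cingulate", "rostral middle frontal",
    "superior frontal", "superior parietal", "superior temporal",
    "supramarginal", "transverse temporal", "insula"
  )
  data.frame(
    code = c(paste0("lh_", abbrev), paste0("rh_", abbrev)),
    abbrev = rep(abbrev, 2L),
    name = rep(name, 2L),
    hemisphere = rep(c("left", "right"), each = 31L),
    stringsAsFactors = FALSE
  )
}

#' Region column names of a thickness table
#'
#' @return Character vector of the 62 region column codes in canonical order.
#' @export
dkt_region_codes <- function() dkt_regions()$code

# Columns preceding the region block in a tidy thickness table.
covariate_columns <- function() {
  c("subject_id", "site", "visit_time_months", "gender", "age_baseline",
    "icv", "diagnosis", "apoe")
}
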