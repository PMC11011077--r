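# Model specification: which size variable enters the Cox model, on which
# scale, and which clinical covariates it is adjusted for.

SIZE_VARIABLES <- c(diameter = "diameter_cm", cv = "cv_cm3", wv = "wv_cm3")
ADJUSTMENT_VARIABLES <- c("age", "sex", "surgery", "oncology", "mgmt")

#' Specify a Cox model for one tumour size variable
#'
#' @param size_variable One of `"diameter"`, `"cv"`, `"wv"`.
#' @param transform `"identity"` (size entered in cm / cm^3) or `"log"`.
#' @param adjustment Character vector of clinical covariates to adjust for:
#'   any of `"age"`, `"sex"`, `"surgery"`, `"oncology"`, `"mgmt"` (empty =
#'   univariable). When `"mgmt"` is included, patients with an unknown MGMT
#'   result are excluded before fitting. Categorical covariates are
#'   dummy-coded against fixed reference levels: male, biopsy, no Stupp,
#'   unmethylated.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("wv", "log", adjustment = "surgery")
#' @export
model_spec <- function(size_variable = c("diameter", "cv", "wv"),
                       transform = c("identity", "log"),
                       adjustment = character()) {
  size_variable <- match.arg(size_variable)
  transform <- match.arg(transform)
  adjustment <- as.character(adjustment)
  bad <- setdiff(adjustment, ADJUSTMENT_VARIABLES)
  if (length(bad) > 0) {
    stop_bad_input("unknown adjustment variable(s): %s",
                   paste(bad, collapse = ", "))
  }
  if (anyDuplicated(adjustment)) {
    stop_bad_input("adjustment variables must be unique")
  }
  structure(
    list(size_variable = size_variable, transform = transform,
         adjustment = adjustment),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec:", spec_label(x), ">\n")
  invisible(x)
}

#' Human-readable label for a model specification
#'
#' @param spec A [model_spec()].
#' @return A string such as `"log(wv) + surgery"`.
#' @export
spec_label <- function(spec) {
  size <- if (spec$transform == "log") {
    paste0("log(", spec$size_variable, ")")
  } else {
    spec$size_variable
  }
  adj <- if (setequal(spec$adjustment, ADJUSTMENT_VARIABLES)) {
    "all"
  } else if (length(spec$adjustment) > 0) {
    paste(spec$adjustment, collapse = " + ")
  } else {
    NULL
  }
  paste(c(size, adj), collapse = " + ")
}

size_term_name <- function(spec) {
  if (spec$transform == "log") paste0("log_", spec$size_variable)
  else spec$size_variable
}

# Build the numeric design matrix and response for a model specification.
# Rows with mgmt = "unknown" are excluded when mgmt is adjusted for; the
# size term is always the first column.
build_design <- function(table, spec) {
  assert_cohort(table)
  keep <- rep(TRUE, nrow(table))
  if ("mgmt" %in% spec$adjustment) keep <- table$mgmt != "unknown"
  tab <- table[keep, , drop = FALSE]

  size_raw <- tab[[SIZE_VARIABLES[[spec$size_variable]]]]
  if (spec$transform == "log" && any(size_raw <= 0)) {
    stop_bad_input("log transform requires strictly positive sizes")
  }
  cols <- list()
  cols[[size_term_name(spec)]] <-
    if (spec$transform == "log") log(size_raw) else size_raw
  for (adj in spec$adjustment) {
    switch(adj,
      age = { cols[["age"]] <- tab$age },
      sex = { cols[["sex_female"]] <- as.numeric(tab$sex == "female") },
      surgery = {
        for (lv in SURGERY_LEVELS[-1]) {
          cols[[paste0("surgery_", lv)]] <- as.numeric(tab$surgery == lv)
        }
      },
      oncology = {
        for (lv in ONCOLOGY_LEVELS[-1]) {
          cols[[paste0("oncology_", lv)]] <- as.numeric(tab$oncology == lv)
        }
      },
      mgmt = {
        cols[["mgmt_methylated"]] <- as.numeric(tab$mgmt == "methylated")
      }
    )
  }
  x <- do.call(cbind, cols)
  list(
    x = x,
    time = tab$time_months,
    event = as.integer(tab$event),
    n_used = nrow(tab),
    n_events = sum(tab$event),
    size_term = size_term_name(spec)
  )
}
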