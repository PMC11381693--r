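#' Load a long-term condition registry
#'
#' The registry is the ordered list of long-term condition (LTC) categories
#' used throughout the pipeline: each entry has a short `condition_id` (the
#' column name used in cohort tables), a human-readable `display_name`, and an
#' optional sex restriction (e.g. endometriosis is only defined for females).
#' The packaged default registry holds the 53 LTC categories of the Delphi
#' consensus list used in multimorbidity research.
#'
#' @param path Path to a registry JSON file
#'   (`[{"condition_id":..., "display_name":..., "sex_restricted":
#'   null|"female"|"male"}, ...]`). `NULL` loads the packaged default.
#' @param allow_nonstandard If `TRUE`, accept registries that do not have the
#'   standard 53 entries (e.g. reduced condition lists for simulation
#'   studies). With the default `FALSE` a wrong entry count is an error.
#' @return An object of class `ltc_registry`: a data frame with columns
#'   `condition_id`, `display_name`, `sex_restricted` (`NA`, `"female"` or
#'   `"male"`), in file order.
#' @examples
#' reg <- load_registry()
#' nrow(reg)  # 53
#' @export
load_registry <- function(path = NULL, allow_nonstandard = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "ltc_registry.json", package = "sarcomb",
                        mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!length(raw)) stop("registry file contains no entries")
  entries <- lapply(raw, function(e) {
    if (is.null(e$condition_id) || is.null(e$display_name)) {
      stop("registry entry missing condition_id or display_name")
    }
    sr <- e$sex_restricted
    if (!is.null(sr) && !sr %in% c("female", "male")) {
      stop("sex_restricted must be null, \"female\" or \"male\", got: ", sr)
    }
    data.frame(condition_id = e$condition_id,
               display_name = e$display_name,
               sex_restricted = if (is.null(sr)) NA_character_ else sr,
               stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, entries)
  dup <- reg$condition_id[duplicated(reg$condition_id)]
  if (length(dup)) {
    stop("duplicate condition_id in registry: ", paste(unique(dup), collapse = ", "))
  }
  if (!allow_nonstandard && nrow(reg) != 53L) {
    stop("registry has ", nrow(reg), " entries, expected 53; ",
         "pass allow_nonstandard = TRUE to use a non-standard condition list")
  }
  class(reg) <- c("ltc_registry", "data.frame")
  reg
}

#' Build a registry object from a data frame (internal constructor)
#' @noRd
as_registry <- function(df, allow_nonstandard = TRUE) {
  stopifnot(all(c("condition_id", "display_name") %in% names(df)))
  if (is.null(df$sex_restricted)) df$sex_restricted <- NA_character_
  if (anyDuplicated(df$condition_id)) stop("duplicate condition_id in registry")
  if (!allow_nonstandard && nrow(df) != 53L) stop("expected 53 registry entries")
  rownames(df) <- NULL
  class(df) <- c("ltc_registry", "data.frame")
  df
}

#' Restrict a registry to the conditions applicable to one sex
#' @noRd
registry_for_sex <- function(registry, sex) {
  keep <- is.na(registry$sex_restricted) | registry$sex_restricted == sex
  as_registry(registry[keep, , drop = FALSE])
}

#' Drop one condition from a registry (sensitivity analyses)
#' @noRd
registry_drop <- function(registry, condition_id) {
  if (!condition_id %in% registry$condition_id) {
    stop("condition not in registry: ", condition_id)
  }
  as_registry(registry[registry$condition_id != condition_id, , drop = FALSE])
}

#' @export
print.ltc_registry <- function(x, ...) {
  cat("<ltc_registry> ", nrow(x), " conditions\n", sep = "")
  n_restricted <- sum(!is.na(x$sex_restricted))
  if (n_restricted) {
    cat("  sex-restricted: ",
        paste0(x$condition_id[!is.na(x$sex_restricted)], " (",
               x$sex_restricted[!is.na(x$sex_restricted)], ")", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
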