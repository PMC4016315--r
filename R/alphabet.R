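# Residue alphabet, chemical categories, temperature classes and the
# default assembly-map (binding order) table.

#' The 20 standard amino-acid one-letter codes
#'
#' Ordered alphabetically. Ambiguity codes (B, Z, X, U) are tolerated on
#' input but excluded from all counts; `-` and `.` are gap characters.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_AMBIGUOUS <- c("B", "Z", "X", "U")
AA_GAP <- c("-", ".")

#' Default chemical-category map for the 20 amino acids
#'
#' Returns a named list partitioning the alphabet into five categories:
#' positive (R, K), negative (D, E), aromatic (F, W, Y), polar
#' (S, T, N, Q, C, H) and nonpolar (G, A, V, L, I, P, M). Histidine is
#' mostly neutral at physiological pH and is filed under polar; pass a
#' modified list to any function accepting `categories` to reassign it.
#'
#' @return Named list of character vectors covering all 20 letters.
#' @export
#' @examples
#' default_category_map()$positive
default_category_map <- function() {
  list(
    positive = c("R", "K"),
    negative = c("D", "E"),
    aromatic = c("F", "W", "Y"),
    polar    = c("S", "T", "N", "Q", "C", "H"),
    nonpolar = c("G", "A", "V", "L", "I", "P", "M")
  )
}

check_category_map <- function(categories) {
  members <- sort(unlist(categories, use.names = FALSE))
  if (!identical(members, sort(AA_ALPHABET))) {
    abort("`categories` must partition the 20 amino-acid letters exactly once each.")
  }
  invisible(categories)
}

#' Default binding-order (assembly map) table for 30S r-proteins
#'
#' Classifies S2-S21 as primary, secondary or tertiary rRNA binders
#' following the classical 30S assembly map: primary proteins bind bare
#' 16S rRNA (S4, S7, S8, S15, S17, S20 - exactly six), secondary
#' proteins require at least one bound primary, tertiary proteins
#' require a primary and a secondary. Override with your own table
#' (columns `protein_name`, `binding_order`) where a different map is
#' preferred.
#'
#' @return A tibble with columns `protein_name` and `binding_order`
#'   (factor: primary < secondary < tertiary).
#' @export
default_binding_order <- function() {
  primary   <- c("S4", "S7", "S8", "S15", "S17", "S20")
  secondary <- c("S5", "S6", "S9", "S11", "S12", "S13", "S16", "S18", "S19")
  tertiary  <- c("S2", "S3", "S10", "S14", "S21")
  tibble(
    protein_name = c(primary, secondary, tertiary),
    binding_order = factor(
      rep(c("primary", "secondary", "tertiary"),
          c(length(primary), length(secondary), length(tertiary))),
      levels = c("primary", "secondary", "tertiary"), ordered = TRUE
    )
  ) %>% arrange(match(.data$protein_name, paste0("S", 2:21)))
}

#' Read a binding-order table from TSV
#'
#' @param path TSV file with columns `protein_name` and `binding_order`
#'   (values primary/secondary/tertiary).
#' @return A tibble like [default_binding_order()].
#' @export
read_binding_order <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("protein_name", "binding_order") %in% names(tbl))) {
    abort("binding-order table needs columns `protein_name` and `binding_order`.")
  }
  bad <- setdiff(unique(tbl$binding_order), c("primary", "secondary", "tertiary"))
  if (length(bad)) {
    abort(paste0("unknown binding_order value(s): ", paste(bad, collapse = ", ")))
  }
  tbl %>%
    mutate(binding_order = factor(.data$binding_order,
                                  levels = c("primary", "secondary", "tertiary"),
                                  ordered = TRUE)) %>%
    as_tibble()
}

#' Classify growth-temperature preference as mesophile or thermophile
#'
#' Species are thermophiles when the optimal growth temperature exceeds
#' 50 degrees C (or the raw four-way category is `thermophile`); the
#' three cooler categories - cryophile (< 10), lower mesophile
#' (10 to < 35) and upper mesophile (35 to 50) - collapse to mesophile.
#' Exactly 50 degrees classifies as mesophile.
#'
#' @param x Numeric optimal temperatures in degrees C, or a character
#'   vector of category labels (`cryophile`, `lower_mesophile`,
#'   `upper_mesophile`, `thermophile`).
#' @return Factor with levels `mesophile`, `thermophile`.
#' @export
#' @examples
#' classify_temperature(c(37, 75))
#' classify_temperature("cryophile")
classify_temperature <- function(x) {
  lv <- c("mesophile", "thermophile")
  if (is.numeric(x)) {
    if (any(!is.finite(x))) abort("temperatures must be finite.")
    return(factor(ifelse(x > 50, "thermophile", "mesophile"), levels = lv))
  }
  x <- as.character(x)
  known <- c("cryophile", "lower_mesophile", "upper_mesophile", "thermophile",
             "mesophile")
  bad <- setdiff(unique(x), known)
  if (length(bad)) {
    abort(paste0("unknown temperature categor", if (length(bad) > 1) "ies: " else "y: ",
                 paste(bad, collapse = ", ")))
  }
  factor(ifelse(x == "thermophile", "thermophile", "mesophile"), levels = lv)
}

#' Four-way growth-temperature category from optimal temperature
#'
#' Cryophile below 10, lower mesophile in [10, 35), upper mesophile in
#' [35, 50], thermophile above 50 (degrees C).
#'
#' @param temp Numeric vector of optimal temperatures.
#' @return Factor with the four category levels.
#' @export
temperature_category <- function(temp) {
  if (any(!is.finite(temp))) abort("temperatures must be finite.")
  lab <- ifelse(temp < 10, "cryophile",
         ifelse(temp < 35, "lower_mesophile",
         ifelse(temp <= 50, "upper_mesophile", "thermophile")))
  factor(lab, levels = c("cryophile", "lower_mesophile", "upper_mesophile",
                         "thermophile"))
}

#' Read a species trait table
#'
#' Expects a TSV with a `species_id` column and either `optimal_temp`
#' (numeric, degrees C) or `category` (four-way label); adds the binary
#' `binary_class` column via [classify_temperature()].
#'
#' @param path TSV file path.
#' @return Tibble with `species_id` and `binary_class` (plus the raw column).
#' @export
read_traits <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"species_id" %in% names(tbl)) abort("trait table needs a `species_id` column.")
  if ("optimal_temp" %in% names(tbl)) {
    tbl$binary_class <- classify_temperature(tbl$optimal_temp)
  } else if ("category" %in% names(tbl)) {
    tbl$binary_class <- classify_temperature(tbl$category)
  } else {
    abort("trait table needs `optimal_temp` or `category`.")
  }
  as_tibble(tbl)
}
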