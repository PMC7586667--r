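# Classical mass units: 1 liang = 10 qian = 100 fen. Fen is the base unit.
.fen_per_unit <- c("两" = 100, "钱" = 10, "分" = 1)

#' Convert classical dose units to fen
#'
#' 1 两 (liang) = 10 钱 (qian) = 100 分 (fen); all doses are
#' expressed in the smallest unit, fen. Conversion is exact for decimal
#' quantities; fractional quantities (classical half-doses) are accepted.
#'
#' @param quantity Positive numeric vector.
#' @param unit Character vector of unit symbols, recycled against `quantity`.
#' @return Dose(s) in fen.
#' @examples
#' normalize_dose(3, "钱") # 30
#' @export
normalize_dose <- function(quantity, unit) {
  if (!is.numeric(quantity) || any(!is.finite(quantity)) || any(quantity <= 0)) {
    abort("dose quantities must be finite and > 0")
  }
  f <- .fen_per_unit[normalize_text(unit)]
  if (any(is.na(f))) {
    abort(sprintf(
      "unknown dose unit in component(s): %s",
      paste(sQuote(unique(unit[is.na(f)])), collapse = ", ")
    ), class = "herbsub_unit_error")
  }
  unname(f * quantity)
}

.component_pattern <- paste0(
  "^(.+?)\\s*([0-9]+(?:\\.[0-9]+)?)\\s*([两钱分])$"
)

#' Parse a prescription component string
#'
#' Components are written `<herb><quantity><unit>`, e.g. `白芍3钱`
#' (3 qian of white peony root). The herb name is the maximal prefix before
#' the numeric token; the quantity may be decimal.
#'
#' @param text Character vector of component strings.
#' @return A tibble with columns `herb`, `quantity`, `unit`, `dose_fen`.
#' @export
parse_component <- function(text) {
  txt <- str_trim(text)
  m <- str_match(txt, .component_pattern)
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(sprintf(
      "cannot parse dose component(s): %s",
      paste(sQuote(txt[bad]), collapse = ", ")
    ), class = "herbsub_parse_error")
  }
  q <- as.numeric(m[, 3])
  tibble(
    herb = normalize_text(m[, 2]),
    quantity = q,
    unit = m[, 4],
    dose_fen = normalize_dose(q, m[, 4])
  )
}

format_component <- function(components) {
  paste0(
    components$herb,
    format(components$quantity, trim = TRUE, scientific = FALSE),
    components$unit
  )
}

validate_prescriptions <- function(prescriptions) {
  prescriptions <- as_tibble(prescriptions)
  needed <- c("rx_id", "indication_text", "components")
  missing <- setdiff(needed, names(prescriptions))
  if (length(missing) > 0) {
    abort(paste0("prescriptions must have columns: ", paste(missing, collapse = ", ")))
  }
  empty <- map_int(prescriptions$components, NROW) == 0
  if (any(empty)) {
    abort(sprintf(
      "prescription(s) with no components: %s",
      paste(prescriptions$rx_id[empty], collapse = ", ")
    ))
  }
  prescriptions
}

#' Read and write a prescription database
#'
#' Prescriptions are stored as UTF-8 TSV with a header row and columns
#' `rx_id`, `components` (component strings joined by `;`),
#' `indication_text` (Chinese free text) and optional `source`. On reading,
#' each component string is parsed with [parse_component()] and the parsed
#' table is kept as a `components` list-column; indication text is
#' Unicode-normalized (NFC).
#'
#' @param path File path.
#' @return A prescription tibble with columns `rx_id`, `indication_text`,
#'   `source`, `components` (list of per-component tibbles).
#' @export
read_prescriptions <- function(path) {
  if (!file.exists(path)) abort(sprintf("prescription file not found: '%s'", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("rx_id", "components", "indication_text") %in% names(raw))) {
    abort("prescription file needs columns rx_id, components, indication_text")
  }
  if (!"source" %in% names(raw)) raw$source <- NA_character_
  comp <- map(str_split(raw$components, ";"), function(x) parse_component(x[nzchar(str_trim(x))]))
  validate_prescriptions(tibble(
    rx_id = raw$rx_id,
    indication_text = normalize_text(raw$indication_text),
    source = raw$source,
    components = comp
  ))
}

#' @rdname read_prescriptions
#' @param prescriptions A prescription tibble.
#' @export
write_prescriptions <- function(prescriptions, path) {
  prescriptions <- validate_prescriptions(prescriptions)
  out <- tibble(
    rx_id = prescriptions$rx_id,
    components = map_chr(prescriptions$components, function(x) paste(format_component(x), collapse = ";")),
    indication_text = prescriptions$indication_text,
    source = prescriptions$source %||% NA_character_
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Per-herb dosage proportions
#'
#' For every prescription, each herb's share of the total dose after
#' conversion to fen. Duplicate entries of one herb within a prescription are
#' summed before computing proportions; proportions sum to 1 within each
#' prescription.
#'
#' @param prescriptions A prescription tibble.
#' @return A tibble with columns `rx_id`, `herb`, `dose_fen`, `proportion`.
#' @export
dosage_proportions <- function(prescriptions) {
  prescriptions <- validate_prescriptions(prescriptions)
  prescriptions |>
    select("rx_id", "components") |>
    unnest("components") |>
    group_by(.data$rx_id, .data$herb) |>
    summarise(dose_fen = sum(.data$dose_fen), .groups = "drop_last") |>
    mutate(proportion = .data$dose_fen / sum(.data$dose_fen)) |>
    ungroup()
}

#' Dosage proportion of one herb in one prescription
#'
#' @param prescription A one-row prescription tibble.
#' @param herb Herb name.
#' @return A fraction in (0, 1].
#' @export
dosage_proportion <- function(prescription, herb) {
  prescription <- validate_prescriptions(prescription)
  if (nrow(prescription) != 1) abort("dosage_proportion() expects a single prescription row")
  props <- dosage_proportions(prescription)
  hit <- props$herb == normalize_text(herb)
  if (!any(hit)) {
    abort(sprintf("herb '%s' is not a component of prescription '%s'", herb, prescription$rx_id),
      class = "herbsub_absent_herb"
    )
  }
  props$proportion[hit]
}
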