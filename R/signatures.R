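# Reading, writing and summarising 96-channel mutational-signature catalogs
# and per-tumour exposure tables. A catalog is kept in long form: one row per
# (signature, class), so per-signature operations are plain grouped verbs.

#' Convert COSMIC-style bracket labels to the "XYZ>XWZ" dialect
#'
#' @param x Character vector of labels, either `"A[C>A]A"` or `"ACA>AAA"`.
#' @return Character vector in `"ACA>AAA"` form.
#' @export
normalize_class_labels <- function(x) {
  bracket <- grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", x)
  out <- x
  out[bracket] <- paste0(
    substr(x[bracket], 1, 1), substr(x[bracket], 3, 3), substr(x[bracket], 7, 7),
    ">",
    substr(x[bracket], 1, 1), substr(x[bracket], 5, 5), substr(x[bracket], 7, 7)
  )
  out
}

validate_signature_probs <- function(class, prob, name = "signature",
                                     tol = 1e-6) {
  expected <- mutation_classes()
  if (anyDuplicated(class)) {
    dup <- class[duplicated(class)][1]
    rlang::abort(sprintf("duplicate mutation-class row '%s' in %s", dup, name))
  }
  missing <- setdiff(expected, class)
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing %d mutation class(es), e.g. %s",
      name, length(missing), missing[1]
    ))
  }
  extra <- setdiff(class, expected)
  if (length(extra) > 0) {
    rlang::abort(sprintf("unknown mutation-class row '%s' in %s", extra[1], name))
  }
  if (any(prob < 0)) {
    rlang::abort(sprintf("negative probability in %s", name))
  }
  s <- sum(prob)
  if (s <= 0) rlang::abort(sprintf("%s has zero total mass", name))
  if (abs(s - 1) > tol) {
    rlang::warn(sprintf("%s sums to %.6g; renormalizing to 1", name, s))
  }
  invisible(NULL)
}

new_sig_catalog <- function(df) {
  df <- dplyr::mutate(df,
    class = factor(.data$class, levels = mutation_classes())
  )
  df <- dplyr::arrange(df, .data$signature, .data$class)
  df <- dplyr::mutate(df, class = as.character(.data$class))
  tibble::as_tibble(df)
}

#' Read a 96-channel signature catalog
#'
#' Accepts the COSMIC SBS tabular layout: one row per mutation class (labels
#' in either the `"T[C>T]A"` or the `"TCA>TTA"` dialect, auto-detected), one
#' column per signature, tab- or comma-separated. Each column is validated
#' (all 96 classes present exactly once, no negative values) and
#' renormalized to sum to 1, with a warning when the raw sum is off by more
#' than `tol`.
#'
#' @param path Path to a TSV/CSV file.
#' @param tol Tolerance on the column sum before a renormalization warning.
#' @return A signature catalog: tibble with columns `signature`, `class`,
#'   `prob`, in COSMIC class order within each signature.
#' @export
read_signature_catalog <- function(path, tol = 1e-6) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(raw) < 2) rlang::abort("catalog must have a label column and >= 1 signature column")
  names(raw)[1] <- "class"
  raw$class <- normalize_class_labels(as.character(raw$class))
  long <- tidyr::pivot_longer(raw, -"class", names_to = "signature",
                              values_to = "prob")
  long <- dplyr::group_by(long, .data$signature)
  out <- dplyr::group_modify(long, function(d, key) {
    validate_signature_probs(d$class, d$prob, name = key$signature[[1]], tol = tol)
    d$prob <- d$prob / sum(d$prob)
    d
  })
  new_sig_catalog(dplyr::ungroup(out))
}

#' Write a signature catalog
#'
#' Writes the wide tab-separated layout with `"XYZ>XWZ"` row labels.
#'
#' @param catalog Signature catalog tibble (`signature`, `class`, `prob`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(catalog, path) {
  wide <- tidyr::pivot_wider(catalog, names_from = "signature",
                             values_from = "prob")
  wide <- dplyr::arrange(
    wide, factor(.data$class, levels = mutation_classes())
  )
  names(wide)[1] <- "MutationClass"
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' The uniform signature
#'
#' Every one of the 96 mutation classes has probability 1/96 ("all mutations
#' occur with equal frequency"). Gain and Loss Ratios computed against the
#' uniform signature equal 1 by construction.
#'
#' @param name Signature name to use in the catalog.
#' @return A one-signature catalog tibble.
#' @export
uniform_signature <- function(name = "uniform") {
  new_sig_catalog(tibble::tibble(
    signature = name, class = mutation_classes(), prob = 1 / 96
  ))
}

#' Extract one signature as a named probability vector
#'
#' @param catalog Signature catalog tibble.
#' @param name Signature name; may be omitted for a one-signature catalog.
#' @return Named numeric vector of length 96 in COSMIC class order.
#' @export
sig_vector <- function(catalog, name = NULL) {
  if (is.null(name)) {
    nms <- unique(catalog$signature)
    if (length(nms) != 1L) {
      rlang::abort("catalog holds several signatures; supply `name`")
    }
    name <- nms
  }
  d <- dplyr::filter(catalog, .data$signature == name)
  if (nrow(d) == 0) rlang::abort(sprintf("no signature named '%s' in catalog", name))
  out <- stats::setNames(d$prob, d$class)[mutation_classes()]
  if (anyNA(out)) rlang::abort(sprintf("signature '%s' is incomplete", name))
  out
}

#' Major substitution types of each signature
#'
#' Returns, per signature, the smallest set of the six pyrimidine
#' substitution types (taken in order of decreasing total signature mass,
#' ties broken by canonical type order) whose cumulative mass strictly
#' exceeds `threshold`. Used to filter observed mutations to the classes
#' that dominate a signature, e.g. C>T for an APOBEC-like signature carrying
#' more than 99% C>T mass.
#'
#' @param catalog Signature catalog tibble.
#' @param threshold Cumulative-mass threshold in (0, 1); strict (`> 0.9`
#'   by default).
#' @return Tibble with columns `signature`, `type`, `type_mass` (one row per
#'   selected type).
#' @export
major_mutation_types <- function(catalog, threshold = 0.9) {
  stopifnot(threshold > 0, threshold < 1)
  masses <- catalog |>
    dplyr::mutate(type = substitution_type(.data$class)) |>
    dplyr::group_by(.data$signature, .data$type) |>
    dplyr::summarise(type_mass = sum(.data$prob), .groups = "drop_last") |>
    dplyr::arrange(
      dplyr::desc(.data$type_mass),
      factor(.data$type, levels = SUBSTITUTION_TYPES),
      .by_group = TRUE
    ) |>
    dplyr::mutate(cum = cumsum(.data$type_mass)) |>
    dplyr::filter(dplyr::lag(.data$cum, default = 0) <= threshold) |>
    dplyr::ungroup()
  dplyr::select(masses, "signature", "type", "type_mass")
}

#' AT-gain and AT-loss fractions of each signature
#'
#' The "+AT" fraction of a signature is its total mass on classes that
#' mutate C or G to A or T (central C>A or C>T); the "-AT" fraction is the
#' mass converting A or T to C or G (central T>C or T>G). C>G and T>A
#' substitutions change neither composition, so `plus_at + minus_at <= 1`.
#'
#' @param catalog Signature catalog tibble.
#' @return Tibble with columns `signature`, `plus_at`, `minus_at`.
#' @export
at_gain_fraction <- function(catalog) {
  catalog |>
    dplyr::mutate(type = substitution_type(.data$class)) |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      plus_at = sum(.data$prob[.data$type %in% c("C>A", "C>T")]),
      minus_at = sum(.data$prob[.data$type %in% c("T>C", "T>G")]),
      .groups = "drop"
    )
}

#' Read a per-tumour signature-exposure table
#'
#' Long TSV with header columns `sample`, `signature` and either `count`
#' (mutations attributed to the signature) or `fraction`. Counts are
#' converted to per-sample fractions.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `sample`, `signature`, `fraction` (and
#'   `count` when provided).
#' @export
read_exposures <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(d)[1:2] <- c("sample", "signature")
  if ("fraction" %in% names(d)) {
    if (any(d$fraction < 0)) rlang::abort("negative exposure fraction")
    tot <- dplyr::summarise(dplyr::group_by(d, .data$sample),
                            s = sum(.data$fraction))
    if (any(tot$s > 1 + 1e-6)) {
      rlang::abort("exposure fractions of a sample exceed 1")
    }
    return(tibble::as_tibble(d))
  }
  if (!"count" %in% names(d)) {
    rlang::abort("exposure table needs a `count` or `fraction` column")
  }
  if (any(d$count < 0)) rlang::abort("negative exposure count")
  d |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}
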