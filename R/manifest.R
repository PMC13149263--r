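#' Declare a cohort variable for harmonization
#'
#' A variable spec describes one raw column: its semantic kind, the
#' direction in which it loads on the risk index, the values considered
#' plausible, and how its codes map onto a harmonized numeric signal.
#'
#' @param name Raw column name in the cohort table.
#' @param kind One of `"continuous"`, `"ordinal"`, `"binary"`, `"nominal"`.
#' @param direction Risk direction: `+1` (higher value, higher risk),
#'   `-1`, or `0` (excluded from the risk index but still harmonized).
#' @param range Length-2 inclusive plausibility bounds; required for
#'   continuous variables. Values outside are treated as implausible.
#' @param codes For ordinal/binary/nominal variables, a named numeric
#'   vector mapping raw codes (names, as character) to encoded values.
#'   Ordinal encodings must be consecutive integers preserving order;
#'   binary encodings must be 0/1. Unlisted codes are treated as missing.
#' @param harmonized_name Target column name after harmonization
#'   (defaults to `name`).
#' @param source_tag Free-text tag naming the dataset of origin.
#' @param na_codes Character vector of sentinel values (refusal codes,
#'   `"NA"`, `"."`, ...) recoded to missing before any other rule.
#' @return A `variable_spec` object.
#' @export
variable_spec <- function(name, kind = c("continuous", "ordinal", "binary", "nominal"),
                          direction = 0, range = NULL, codes = NULL,
                          harmonized_name = name, source_tag = "unknown",
                          na_codes = character()) {
  kind <- match.arg(kind)
  if (!direction %in% c(-1, 0, 1)) stop("`direction` must be -1, 0 or +1")
  if (kind == "continuous") {
    if (is.null(range) || length(range) != 2L || !all(is.finite(range)) ||
        range[1] >= range[2])
      stop("continuous variable '", name, "' needs finite range with lower < upper")
  } else {
    if (is.null(codes) || is.null(names(codes)))
      stop("categorical variable '", name, "' needs a named `codes` mapping")
    codes <- stats::setNames(as.numeric(codes), names(codes))
    if (kind == "binary" && !setequal(unique(unname(codes)), c(0, 1)))
      stop("binary variable '", name, "' must encode to {0, 1}")
  }
  structure(
    list(name = name, kind = kind, direction = direction, range = range,
         codes = codes, harmonized_name = harmonized_name,
         source_tag = source_tag, na_codes = as.character(na_codes)),
    class = "variable_spec"
  )
}

#' Assemble a variable manifest
#'
#' @param ... `variable_spec` objects (or a single list of them).
#' @return A `variable_manifest`: a validated list of specs.
#' @export
variable_manifest <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && !inherits(entries[[1]], "variable_spec"))
    entries <- entries[[1]]
  if (!length(entries)) stop("manifest needs at least one variable")
  ok <- vapply(entries, inherits, logical(1), "variable_spec")
  if (!all(ok)) stop("all manifest entries must be variable_spec objects")
  hn <- vapply(entries, `[[`, character(1), "harmonized_name")
  if (anyDuplicated(hn)) stop("duplicate harmonized_name: ",
                              paste(unique(hn[duplicated(hn)]), collapse = ", "))
  names(entries) <- vapply(entries, `[[`, character(1), "name")
  structure(entries, class = "variable_manifest")
}

#' Read a variable manifest from YAML
#'
#' Each YAML entry carries keys `name`, `kind`, `direction`,
#' `range`/`codes`, `harmonized_name`, `source`, `na_codes`.
#'
#' @param path Path to a YAML manifest file.
#' @return A `variable_manifest`.
#' @export
read_manifest <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(e) {
    codes <- e$codes
    if (!is.null(codes)) codes <- stats::setNames(as.numeric(unlist(codes)), names(codes))
    variable_spec(
      name = e$name, kind = e$kind, direction = e$direction %||% 0,
      range = if (!is.null(e$range)) as.numeric(unlist(e$range)),
      codes = codes,
      harmonized_name = e$harmonized_name %||% e$name,
      source_tag = e$source %||% "unknown",
      na_codes = as.character(e$na_codes %||% character())
    )
  })
  variable_manifest(specs)
}

#' Write a variable manifest to YAML
#'
#' @param manifest A `variable_manifest`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- lapply(unclass(manifest), function(e) {
    lst <- list(name = e$name, kind = e$kind, direction = e$direction,
                harmonized_name = e$harmonized_name, source = e$source_tag)
    if (!is.null(e$range)) lst$range <- as.numeric(e$range)
    if (!is.null(e$codes)) lst$codes <- as.list(stats::setNames(unname(e$codes), names(e$codes)))
    if (length(e$na_codes)) lst$na_codes <- e$na_codes
    lst
  })
  yaml::write_yaml(unname(out), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.variable_manifest <- function(x, ...) {
  cat("Variable manifest:", length(x), "variables\n")
  for (e in x)
    cat(sprintf("  %-20s %-10s dir %+d -> %s\n", e$name, e$kind,
                e$direction, e$harmonized_name))
  invisible(x)
}
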