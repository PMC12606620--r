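#' Read spectra from delimited text
#'
#' The CSV dialect is two columns (`shift_cm1`, `intensity`) per spectrum
#' with `#`-prefixed metadata header lines (`# key: value`); multi-spectrum
#' files carry an additional leading `spectrum` column.  The axis must be
#' uniform and increasing.
#'
#' @param path file path.
#' @return list of `raman_spectrum` objects (empty list, with a warning,
#'   for an empty file).
#' @export
read_spectra <- function(path) {
  if (!file.exists(path))
    stop_etalon("etalonsim_parse", "file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    warning(sprintf("empty spectra file '%s'", path))
    return(list())
  }
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    i <- regexpr(":", kv)
    if (i > 0)
      meta[[trimws(substr(kv, 1, i - 1))]] <- trimws(substr(kv, i + 1, nchar(kv)))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- tryCatch(utils::read.csv(text = body, header = TRUE),
                 error = function(e)
                   stop_etalon("etalonsim_parse", "cannot parse '%s': %s",
                               path, conditionMessage(e)))
  if (!all(c("shift_cm1", "intensity") %in% names(df)))
    stop_etalon("etalonsim_parse",
                "'%s' must have columns shift_cm1, intensity", path)
  excitation <- as.numeric(meta[["excitation_nm"]] %||% 785)
  split_ids <- if ("spectrum" %in% names(df)) df$spectrum else rep(1L, nrow(df))
  lapply(split(df, split_ids), function(d) {
    if (any(diff(d$shift_cm1) <= 0))
      stop_etalon("etalonsim_parse", "non-monotone axis in '%s'", path)
    raman_spectrum(d$shift_cm1, d$intensity, excitation, metadata = meta)
  })
}

#' Write spectra to delimited text
#'
#' Inverse of [read_spectra()].
#'
#' @param spectra a `raman_spectrum` or list of them (shared axis).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  hdr <- c(sprintf("# excitation_nm: %g", spectra[[1]]$excitation_nm),
           sprintf("# n_spectra: %d", length(spectra)))
  rows <- do.call(rbind, lapply(seq_along(spectra), function(i)
    data.frame(spectrum = i, shift_cm1 = spectra[[i]]$shift_cm1,
               intensity = spectra[[i]]$intensity)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Write a pair set to a directory of delimited text files
#'
#' `axis.csv`, `clean.csv`, `corrupted.csv` (spectra as rows) and a
#' `meta.yaml` with recipe, design assignments and seed.  Text-only,
#' round-trips bit-identically through [read_pairs()].
#'
#' @param pairs a `pair_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pairs <- function(pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) utils::write.table(
    format(x, digits = 17, scientific = TRUE, trim = TRUE),
    file.path(dir, f), sep = ",", row.names = FALSE, col.names = FALSE,
    quote = FALSE)
  wr(matrix(pairs$axis, 1), "axis.csv")
  wr(pairs$clean, "clean.csv")
  wr(pairs$corrupted, "corrupted.csv")
  yaml::write_yaml(list(recipe = pairs$recipe,
                        design_id = as.integer(pairs$design_id),
                        seed = pairs$seed,
                        dark_current = pairs$dark_current),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a pair set written by [write_pairs()]
#' @param dir directory path.
#' @return a `pair_set`.
#' @export
read_pairs <- function(dir) {
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = ","))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  out <- list(axis = as.numeric(rd("axis.csv")),
              clean = unname(rd("clean.csv")),
              corrupted = unname(rd("corrupted.csv")),
              design_id = as.integer(meta$design_id), recipe = meta$recipe,
              seed = meta$seed)
  if (!is.null(meta$dark_current)) out$dark_current <- meta$dark_current
  structure(out, class = "pair_set")
}

#' Read a stack definition from YAML
#'
#' Dialect: `incident`, `substrate` (material names) and `layers`, an
#' ordered list of `{material, thickness_nm}`.
#'
#' @param path YAML file path.
#' @return a `tmm_stack`.
#' @export
read_stack <- function(path) {
  y <- yaml::read_yaml(path)
  optical_stack(lapply(y$layers, function(l) layer(l$material, l$thickness_nm)),
                incident = material(y$incident %||% "air"),
                substrate = material(y$substrate %||% "air"))
}

#' Write a stack definition to YAML
#' @param stack a `tmm_stack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  yaml::write_yaml(list(
    incident = stack$incident$material_id,
    substrate = stack$substrate$material_id,
    layers = lapply(stack$layers, function(l)
      list(material = l$material$material_id, thickness_nm = l$thickness_nm))),
    path)
  invisible(path)
}
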