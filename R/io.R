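# File formats: a TRIPOS mol2 subset, TSV time series and PMFs, CSV
# window manifests and pair overrides, YAML atom-type tables, JSON
# results. Plain text only.

#' Read a mol2 file (TRIPOS subset)
#'
#' Parses the @<TRIPOS>MOLECULE and @<TRIPOS>ATOM sections; any other
#' record type is skipped with a message. Atom records yield names,
#' coordinates (A), SYBYL types and partial charges.
#'
#' @param path File path.
#' @return List with `molecule` (name), `names`, `coordinates` (n x 3
#'   matrix), `types`, `charges`.
#' @export
read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec_at <- grep("^@<TRIPOS>", lines)
  if (!any(grepl("^@<TRIPOS>MOLECULE", lines)))
    stop("mol2 format error: missing @<TRIPOS>MOLECULE section")
  atom_start <- grep("^@<TRIPOS>ATOM", lines)
  if (length(atom_start) == 0)
    stop(sprintf(paste0("mol2 format error at line %d: missing ",
                        "@<TRIPOS>ATOM section"), length(lines)))
  known <- c("@<TRIPOS>MOLECULE", "@<TRIPOS>ATOM")
  other <- setdiff(sub("\\s.*$", "", lines[sec_at]), known)
  if (length(other))
    message("mol2: skipping unsupported sections: ",
            paste(unique(other), collapse = ", "))
  mol_start <- grep("^@<TRIPOS>MOLECULE", lines)[1]
  mol_name <- trimws(lines[mol_start + 1])
  atom_start <- atom_start[1]
  nxt <- sec_at[sec_at > atom_start]
  atom_end <- if (length(nxt)) min(nxt) - 1 else length(lines)
  rows <- lines[(atom_start + 1):atom_end]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) == 0)
    stop(sprintf("mol2 format error at line %d: empty ATOM section",
                 atom_start))
  tok <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(tok, length, 1L) < 9)
  if (length(bad))
    stop(sprintf("mol2 format error at line %d: short ATOM record",
                 atom_start + bad[1]))
  m <- do.call(rbind, tok)
  list(molecule = mol_name,
       names = m[, 2],
       coordinates = matrix(as.numeric(m[, 3:5]), ncol = 3,
                            dimnames = list(m[, 2], c("x", "y", "z"))),
       types = m[, 6],
       charges = as.numeric(m[, 9]))
}

#' Write a mol2 file (TRIPOS subset)
#'
#' @param path Output path.
#' @param molecule Molecule name.
#' @param names Atom names.
#' @param coordinates n x 3 matrix, A.
#' @param types SYBYL atom types.
#' @param charges Partial charges, e.
#' @return `path`, invisibly.
#' @export
write_mol2 <- function(path, molecule, names, coordinates, types,
                       charges) {
  n <- length(names)
  stopifnot(nrow(coordinates) == n, length(types) == n,
            length(charges) == n)
  out <- c("@<TRIPOS>MOLECULE", molecule,
           sprintf("%d 0 1 0 0", n), "SMALL", "USER_CHARGES", "",
           "@<TRIPOS>ATOM",
           sprintf("%7d %-8s %10.4f %10.4f %10.4f %-6s %3d %-8s %10.6f",
                   seq_len(n), names, coordinates[, 1], coordinates[, 2],
                   coordinates[, 3], types, 1L, "RES1", charges))
  writeLines(out, path)
  invisible(path)
}

#' Write a sampled time series as 2-column TSV
#'
#' Header lines (prefixed `#`) carry the seed and any lambda/window
#' metadata; data rows are (step, value).
#'
#' @param ts A `time_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  meta <- ts$meta[!vapply(ts$meta, is.null, TRUE)]
  meta <- meta[vapply(meta, function(m) is.atomic(m) && length(m) == 1,
                      TRUE)]
  hdr <- sprintf("# %s=%s", names(meta),
                 vapply(meta, function(v) format(v, digits = 15), ""))
  writeLines(c(hdr, "# step\tvalue",
               sprintf("%d\t%.10g", seq_along(ts$values), ts$values)),
             path)
  invisible(path)
}

#' Read a time series written by [write_series_tsv()]
#' @param path File path.
#' @return A `time_series` (acceptance NA; metadata from the header).
#' @export
read_series_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^# *([A-Za-z_.]+)=(.*)$", h))[[1]]
    if (length(kv) == 3) {
      v <- suppressWarnings(as.numeric(kv[3]))
      meta[[kv[2]]] <- if (is.na(v)) kv[3] else v
    }
  }
  dat <- lines[!grepl("^#", lines)]
  dat <- dat[nzchar(dat)]
  vals <- vapply(strsplit(dat, "\t"), function(x) as.numeric(x[2]),
                 numeric(1))
  new_time_series(vals, NA_real_, meta)
}

#' Write a window manifest (CSV: window_id, r0, k_rest, path)
#' @param windows List of [us_window()] objects.
#' @param dir Output directory (created if absent); one TSV per window
#'   plus `manifest.csv`.
#' @return Manifest path, invisibly.
#' @export
write_window_set <- function(windows, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    f <- file.path(dir, sprintf("window_%03d.tsv", i))
    ts <- w$series
    ts$meta$window <- i
    ts$meta$r0 <- w$restraint$r0
    ts$meta$k_rest <- w$restraint$k_rest
    write_series_tsv(ts, f)
    data.frame(window_id = i, r0 = w$restraint$r0,
               k_rest = w$restraint$k_rest, path = basename(f))
  })
  mf <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), mf, row.names = FALSE)
  invisible(mf)
}

#' Read a window set from a manifest written by [write_window_set()]
#' @param manifest Path to `manifest.csv`.
#' @return List of [us_window()] objects.
#' @export
read_window_set <- function(manifest) {
  df <- read.csv(manifest)
  need <- c("window_id", "r0", "k_rest", "path")
  if (!all(need %in% names(df)))
    stop("window manifest needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    ts <- read_series_tsv(file.path(dirname(manifest), df$path[i]))
    us_window(restraint_spec(df$k_rest[i], df$r0[i]), ts)
  })
}

#' Write a PMF profile as TSV (bin_center, delta_G, n_eff)
#' @param pmf A `pmf_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(pmf, path) {
  writeLines(c("# bin_center\tdelta_G\tn_eff",
               sprintf("%.5f\t%s\t%d", pmf$bin_centers,
                       ifelse(is.finite(pmf$free_energy),
                              sprintf("%.6f", pmf$free_energy), "NA"),
                       as.integer(pmf$n_eff))), path)
  invisible(path)
}

#' Write a landmark set as JSON
#' @param lm A `landmark_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(lm, path) {
  jsonlite::write_json(as.data.frame(lm), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an atom-type table from YAML
#'
#' Expected layout: a top-level `atom_types` map of
#' `name: {Q: ..., C12: ..., C6: ..., alpha0: ...}` entries (absent fields
#' default to 0).
#'
#' @param path YAML file path.
#' @return Named list of [atom_type()] objects.
#' @export
read_atom_types <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$atom_types)) stop("no atom_types map in ", path)
  out <- lapply(names(doc$atom_types), function(nm) {
    e <- doc$atom_types[[nm]]
    atom_type(nm, Q = e$Q %||% 0, C12 = e$C12 %||% 0, C6 = e$C6 %||% 0,
              alpha0 = e$alpha0 %||% 0)
  })
  setNames(out, names(doc$atom_types))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read pair-coefficient overrides from CSV
#'
#' Columns: type_i, type_j, C12, C6, C4. Combined with per-type charges
#' into a [pair_table()].
#'
#' @param path CSV path.
#' @param charges Optional named numeric vector of per-type charges (e).
#' @return A [pair_table()].
#' @export
read_pair_overrides <- function(path, charges = NULL) {
  pair_table(read.csv(path), charges = charges)
}
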