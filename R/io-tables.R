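AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

SHIFT_ATOMS <- c("H", "N", "CA", "CB", "CO")

#' Assigned backbone chemical-shift table
#'
#' One row per (residue, atom) with the shift in ppm. Duplicate
#' (residue, atom) pairs are an error; 1H shifts outside `[5, 13]` ppm and
#' 15N shifts outside `[100, 140]` ppm only produce a warning, since
#' unusual but genuine shifts occur.
#'
#' @param residue_number Integer residue numbers (full-length numbering).
#' @param residue_type One-letter residue codes.
#' @param atom Atom names, each one of H, N, CA, CB, CO.
#' @param shift Chemical shifts (ppm).
#' @return `data.frame` of class `shift_table`.
#' @export
shift_table <- function(residue_number, residue_type, atom, shift) {
  atom <- toupper(atom)
  bad <- setdiff(unique(atom), SHIFT_ATOMS)
  if (length(bad)) stop("unknown atom name(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(shift))) stop("non-finite chemical shift")
  df <- data.frame(residue_number = as.integer(residue_number),
                   residue_type = toupper(residue_type),
                   atom = atom, shift = as.numeric(shift),
                   stringsAsFactors = FALSE)
  key <- paste(df$residue_number, df$atom)
  if (anyDuplicated(key))
    stop("duplicate (residue, atom) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  odd_h <- df$atom == "H" & (df$shift < 5 | df$shift > 13)
  odd_n <- df$atom == "N" & (df$shift < 100 | df$shift > 140)
  if (any(odd_h | odd_n))
    warning(sum(odd_h | odd_n),
            " H/N shift(s) outside the typical backbone range")
  class(df) <- c("shift_table", "data.frame")
  df
}

#' Extract one atom's shifts as a named vector
#' @param tab A [shift_table()].
#' @param which_atom Atom name.
#' @return Numeric vector of shifts named by residue number.
#' @export
atom_shifts <- function(tab, which_atom) {
  sel <- tab[tab$atom == toupper(which_atom), ]
  stats::setNames(sel$shift, sel$residue_number)
}

detect_delim <- function(lines) {
  probe <- lines[nzchar(lines) & !startsWith(lines, "#")][1]
  if (is.na(probe)) stop("file has no data lines")
  counts <- vapply(c(",", "\t", ";"),
                   function(d) lengths(regmatches(probe, gregexpr(d, probe, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0)) stop("could not detect a delimiter (',', tab, ';')")
  names(counts)[which.max(counts)]
}

read_delim_auto <- function(path) {
  lines <- readLines(path, warn = FALSE)
  delim <- detect_delim(lines)
  utils::read.table(text = lines, sep = delim, header = TRUE,
                    comment.char = "#", stringsAsFactors = FALSE,
                    strip.white = TRUE, check.names = FALSE)
}

#' Read an assigned chemical-shift table
#'
#' Supported dialects:
#' \describe{
#'   \item{`csv`}{Delimited text (comma/tab/semicolon auto-detected) with
#'     columns `residue`, `residue_type`, `atom`, `shift`.}
#'   \item{`sparky_list`}{Sparky peak list with `T123N-H  w1  w2 [height]`
#'     assignment lines; the 15N shift is `w1`, the 1H shift `w2`, and any
#'     height column is returned in the `intensities` attribute.}
#'   \item{`nmrstar_loop`}{Minimal NMR-STAR v3 reader restricted to the
#'     `_Atom_chem_shift` loop (as in BMRB depositions).}
#' }
#'
#' @param path Input file.
#' @param dialect One of `"csv"`, `"sparky_list"`, `"nmrstar_loop"`.
#' @param number_offset Added to every residue number on read, for
#'   depositions in construct-local numbering.
#' @return A [shift_table()]; for Sparky lists with heights, attribute
#'   `intensities` holds a `data.frame(residue_number, intensity)`.
#' @export
read_shift_table <- function(path, dialect = c("csv", "sparky_list", "nmrstar_loop"),
                             number_offset = 0L) {
  dialect <- match.arg(dialect)
  out <- switch(dialect,
                csv = read_shift_csv(path),
                sparky_list = read_shift_sparky(path),
                nmrstar_loop = read_shift_nmrstar(path))
  if (number_offset != 0L) {
    out$residue_number <- out$residue_number + as.integer(number_offset)
    ints <- attr(out, "intensities")
    if (!is.null(ints)) {
      ints$residue_number <- ints$residue_number + as.integer(number_offset)
      attr(out, "intensities") <- ints
    }
  }
  out
}

read_shift_csv <- function(path) {
  df <- read_delim_auto(path)
  names(df) <- tolower(names(df))
  need <- c("residue", "residue_type", "atom", "shift")
  if (!all(need %in% names(df)))
    stop("shift CSV needs columns: ", paste(need, collapse = ", "))
  shift_table(df$residue, df$residue_type, df$atom, df$shift)
}

read_shift_sparky <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^Assignment", lines)]
  res_no <- integer(0); res_ty <- character(0)
  atom <- character(0); shift <- numeric(0)
  int_res <- integer(0); int_val <- numeric(0)
  pat <- "^([A-Z])(\\d+)([A-Z]+[0-9]*)-([A-Z]+[0-9]*)$"
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (length(parts) < 3)
      stop(sprintf("line %d: expected 'assignment w1 w2 [height]'", i))
    lab <- parts[1]
    if (!grepl(pat, lab))
      stop(sprintf("line %d: unparsable assignment label '%s'", i, lab))
    ty <- sub(pat, "\\1", lab)
    no <- as.integer(sub(pat, "\\2", lab))
    a1 <- sub(pat, "\\3", lab); a2 <- sub(pat, "\\4", lab)
    w <- suppressWarnings(as.numeric(parts[2:3]))
    if (any(is.na(w))) stop(sprintf("line %d: non-numeric shift", i))
    res_no <- c(res_no, no, no); res_ty <- c(res_ty, ty, ty)
    atom <- c(atom, a1, a2); shift <- c(shift, w[1], w[2])
    if (length(parts) >= 4) {
      h <- suppressWarnings(as.numeric(parts[4]))
      if (!is.na(h)) { int_res <- c(int_res, no); int_val <- c(int_val, h) }
    }
  }
  tab <- shift_table(res_no, res_ty, atom, shift)
  if (length(int_res))
    attr(tab, "intensities") <- data.frame(residue_number = int_res,
                                           intensity = int_val)
  tab
}

# Tokenise one NMR-STAR data row (values may be single-quoted).
star_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line)[[1]]
  toks <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

read_shift_nmrstar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lt <- trimws(lines)
  loop_starts <- which(lt == "loop_")
  if (!length(loop_starts)) stop("no loop_ found in NMR-STAR file")
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character(0)
    while (i <= length(lt) && startsWith(lt[i], "_")) {
      tags <- c(tags, lt[i]); i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    short <- sub("^_Atom_chem_shift\\.", "", tags)
    rows <- list()
    while (i <= length(lt) && lt[i] != "stop_") {
      if (nzchar(lt[i]) && !startsWith(lt[i], "#"))
        rows[[length(rows) + 1L]] <- star_tokens(lt[i])
      i <- i + 1L
    }
    if (!length(rows)) stop("empty _Atom_chem_shift loop")
    nbad <- which(lengths(rows) != length(tags))
    if (length(nbad)) stop("malformed NMR-STAR row ", nbad[1])
    mat <- do.call(rbind, rows)
    colnames(mat) <- short
    col <- function(...) {
      for (nm in c(...)) if (nm %in% short) return(mat[, nm])
      stop("NMR-STAR loop lacks required tag: ", ..1)
    }
    seq_id <- as.integer(col("Seq_ID", "Comp_index_ID"))
    comp <- toupper(col("Comp_ID"))
    ty <- AA3TO1[comp]
    if (any(is.na(ty))) stop("unknown residue name: ",
                             comp[which(is.na(ty))[1]])
    atom_id <- toupper(col("Atom_ID"))
    atom_id[atom_id == "C"] <- "CO"
    keep <- atom_id %in% SHIFT_ATOMS
    val <- as.numeric(col("Val"))
    return(shift_table(seq_id[keep], ty[keep], atom_id[keep], val[keep]))
  }
  stop("no _Atom_chem_shift loop found in NMR-STAR file")
}

#' Titration design: observed-protein concentration and partner admixtures
#'
#' Partner amounts given as percentages ("50%") are converted to uM as
#' `percent * a_total / 100` at construction time, matching how admixtures
#' are quoted in titration experiments; plain numbers or "x uM" strings are
#' taken as uM.
#'
#' @param a_total Concentration of the observed (labeled) protein, uM.
#' @param points `data.frame` with columns `label` (unique) and `b` (number
#'   in uM, or string with `%`/`uM` suffix).
#' @param partner_id Name of the titrated partner.
#' @return Object of class `titration_design` with `points$b_total` in uM.
#' @export
titration_design <- function(a_total, points, partner_id = "partner") {
  stopifnot(a_total > 0, is.data.frame(points),
            all(c("label", "b") %in% names(points)))
  if (anyDuplicated(points$label)) stop("point labels must be unique")
  b_total <- vapply(points$b, parse_conc, numeric(1), a_total = a_total)
  if (any(b_total < 0)) stop("partner concentrations must be >= 0")
  structure(list(a_total = a_total, partner_id = partner_id,
                 points = data.frame(label = as.character(points$label),
                                     b_total = b_total,
                                     stringsAsFactors = FALSE)),
            class = "titration_design")
}

parse_conc <- function(x, a_total) {
  if (is.numeric(x)) return(as.numeric(x))
  s <- trimws(as.character(x))
  if (grepl("%$", s)) return(as.numeric(sub("%$", "", s)) * a_total / 100)
  s <- sub("[ ]*[uµ]M$", "", s)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("cannot parse concentration: ", x)
  v
}

#' Read a titration design from delimited text
#'
#' Expects columns `label` and `b` (values like `50%` or `120uM` or plain
#' uM numbers); `a_total` and `partner_id` are passed by the caller.
#' @param path File path.
#' @inheritParams titration_design
#' @return A [titration_design()].
#' @export
read_titration_design <- function(path, a_total, partner_id = "partner") {
  df <- read_delim_auto(path)
  names(df) <- tolower(names(df))
  titration_design(a_total, df[, c("label", "b")], partner_id)
}

#' Magnetization decay table
#' @param residue_number,delay_s,intensity,intensity_error Column vectors.
#' @return `data.frame` of class `decay_table`. At least 3 distinct delays
#'   per residue, all delays and errors > 0.
#' @export
decay_table <- function(residue_number, delay_s, intensity, intensity_error) {
  stopifnot(all(delay_s > 0), all(intensity_error > 0))
  df <- data.frame(residue_number = as.integer(residue_number),
                   delay_s = as.numeric(delay_s),
                   intensity = as.numeric(intensity),
                   intensity_error = as.numeric(intensity_error))
  ndelay <- tapply(df$delay_s, df$residue_number,
                   function(d) length(unique(d)))
  if (any(ndelay < 3))
    stop("residue(s) with fewer than 3 distinct delays: ",
         paste(names(ndelay)[ndelay < 3], collapse = ", "))
  class(df) <- c("decay_table", "data.frame")
  df
}

#' Read a decay table (columns residue, delay_s, intensity, error)
#' @param path File path.
#' @return A [decay_table()].
#' @export
read_decay_table <- function(path) {
  df <- read_delim_auto(path)
  names(df) <- tolower(names(df))
  need <- c("residue", "delay_s", "intensity", "error")
  if (!all(need %in% names(df)))
    stop("decay table needs columns: ", paste(need, collapse = ", "))
  decay_table(df$residue, df$delay_s, df$intensity, df$error)
}

#' CPMG dispersion table
#'
#' Accepts either explicit `r2eff` or `intensity` + `ref_intensity`
#' (converted with [r2eff_from_intensities()]). Errors are floored at
#' `error_floor` (s^-1).
#'
#' @param df `data.frame` with columns `residue`, `field_mhz`, `t_relax_s`,
#'   `nu_cpmg_hz`, `error`, and either `r2eff` or
#'   `intensity` + `ref_intensity`.
#' @param error_floor Minimum point error in s^-1 (default 0.5).
#' @return `data.frame` of class `dispersion_table` with columns
#'   `residue_number, field_mhz, t_relax_s, nu_cpmg_hz, r2eff, error`.
#' @export
dispersion_table <- function(df, error_floor = 0.5) {
  names(df) <- tolower(names(df))
  need <- c("residue", "field_mhz", "t_relax_s", "nu_cpmg_hz", "error")
  if (!all(need %in% names(df)))
    stop("dispersion table needs columns: ", paste(need, collapse = ", "))
  stopifnot(all(df$t_relax_s > 0), all(df$nu_cpmg_hz > 0))
  if ("r2eff" %in% names(df)) {
    r2 <- df$r2eff
  } else if (all(c("intensity", "ref_intensity") %in% names(df))) {
    r2 <- r2eff_from_intensities(df$intensity, df$ref_intensity, df$t_relax_s)
  } else stop("need either an r2eff column or intensity + ref_intensity")
  out <- data.frame(residue_number = as.integer(df$residue),
                    field_mhz = df$field_mhz, t_relax_s = df$t_relax_s,
                    nu_cpmg_hz = df$nu_cpmg_hz, r2eff = r2,
                    error = pmax(df$error, error_floor))
  keep <- is.finite(out$r2eff)
  if (any(!keep))
    warning(sum(!keep), " dispersion point(s) dropped (broadened beyond detection)")
  out <- out[keep, ]
  class(out) <- c("dispersion_table", "data.frame")
  out
}

#' Read a CPMG dispersion table
#' @param path File path.
#' @param error_floor Minimum point error in s^-1.
#' @return A [dispersion_table()].
#' @export
read_dispersion_table <- function(path, error_floor = 0.5) {
  dispersion_table(read_delim_auto(path), error_floor = error_floor)
}

#' ITC injection table
#' @param cell_conc,syringe_conc Concentrations (uM).
#' @param cell_volume Active cell volume (uL).
#' @param injections `data.frame(volume_uL, heat_ucal)` in injection order.
#' @param exclude_first Flag the first injection as excluded from fits.
#' @return Object of class `itc_table`.
#' @export
itc_table <- function(cell_conc, syringe_conc, cell_volume, injections,
                      exclude_first = TRUE) {
  stopifnot(cell_conc > 0, syringe_conc > 0, cell_volume > 0,
            all(c("volume_uL", "heat_ucal") %in% names(injections)),
            all(injections$volume_uL > 0))
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_volume = cell_volume,
                 injections = as.data.frame(injections),
                 exclude_first = isTRUE(exclude_first)),
            class = "itc_table")
}

#' Read an ITC injection table
#'
#' CSV with columns `volume_uL, heat_ucal` plus header comment lines
#' `# cell_conc_uM: 30`, `# syringe_conc_uM: 300`, `# cell_volume_uL: 200`.
#' @param path File path.
#' @param exclude_first Flag the first injection as excluded.
#' @return An [itc_table()].
#' @export
read_itc_table <- function(path, exclude_first = TRUE) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(trimws(lines), "#")]
  get_meta <- function(key) {
    hit <- grep(paste0(key, "\\s*:"), hdr, value = TRUE)
    if (!length(hit)) stop("ITC file header missing '# ", key, ": <value>'")
    as.numeric(sub(".*:\\s*", "", hit[1]))
  }
  df <- read_delim_auto(path)
  itc_table(get_meta("cell_conc_uM"), get_meta("syringe_conc_uM"),
            get_meta("cell_volume_uL"),
            df[, c("volume_uL", "heat_ucal")], exclude_first)
}

#' Write result tables and summaries to a directory
#'
#' `data.frame` elements are written as TSV (`<name>.tsv`, full precision,
#' so a read-back round trip reproduces the values); list elements as JSON
#' (`<name>.json`). Empty tables produce a header-only file with a warning.
#'
#' @param tables Named list of `data.frame`s and/or lists.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      if (nrow(x) == 0) warning("table '", nm, "' is empty; header-only file")
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      df <- as.data.frame(x)
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
      utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    } else if (is.list(x)) {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
    } else stop("element '", nm, "' is neither data.frame nor list")
    written <- c(written, f)
  }
  invisible(written)
}

#' Read back a TSV written by [write_results()]
#' @param path File path.
#' @return `data.frame` with numeric columns restored.
#' @export
read_results_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df
}
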