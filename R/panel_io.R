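## Readers and writers for measurement tables, localization annotation and
## result exports. The canonical on-disk format is a long, one-row-per-well
## delimited table; plate-matrix vendor exports should be reshaped to it
## before import.

.CANONICAL <- c(plate = "plate", well = "well", pair = "pair", role = "role",
                experiment = "experiment", donor = "donor",
                acceptor = "acceptor",
                swl_lum = "swl_lum", lwl_lum = "lwl_lum",
                cell_fluor = "cell_fluor", nl_in = "nl_in",
                mcit_in = "mcit_in", nl_out = "nl_out", mcit_out = "mcit_out")

#' Read a long-format measurement table into a LuthyScreen
#'
#' Parses a delimited text table with one row per well. Required columns
#' (after applying `schema`): `plate`, `well`, `pair`, `role` and at least
#' one measurement channel. Optional columns: `experiment` (replicate label,
#' default "1"), `donor`/`acceptor` (construct ids used to resolve shared
#' single-tag controls; synthesized from the pair id when absent) and the
#' remaining channels. Unknown columns are preserved in
#' `metadata$extra_columns`. Missing channels are recorded as absent, never
#' as zero; a dataset without the co-precipitation channels is flagged
#' BRET-only and refused by LuC operations.
#'
#' @param file path to a delimited text file, or a character vector of lines.
#' @param schema optional named character vector mapping canonical names
#'   (names) to the column names used in the file (values), e.g.
#'   `c(plate = "Plate", swl_lum = "Lum470")`.
#' @param delim field delimiter; by default inferred from the file extension
#'   (`.csv` is comma, anything else tab).
#' @param plateFormat "384", "96" or "auto" (96 if all wells fit A1-H12).
#' @param constructs optional construct annotation data.frame with columns
#'   `construct_id`, `protein`, `tag_kind`, `orientation`; inferred from
#'   well roles when omitted.
#'
#' @details When the table has no `donor`/`acceptor` columns, control wells
#' must carry the same pair id as the interaction they control for, so that
#' the loader can associate them by construct identity.
#' @return A [LuthyScreen-class].
#' @examples
#' txt <- c("plate\twell\tpair\trole\tswl_lum\tlwl_lum",
#'          "P1\tA1\tp1\tinteraction\t1000\t300",
#'          "P1\tA2\tp1\tcontrol1\t900\t190",
#'          "P1\tA3\tp1\tcontrol2\t1100\t230",
#'          "P1\tA4\tpanl\tpanl\t1000\t200")
#' scr <- readMeasurements(txt)
#' hasLuc(scr)  # FALSE: BRET-only table
#' @export
readMeasurements <- function(file, schema = NULL, delim = NULL,
                             plateFormat = c("auto", "384", "96"),
                             constructs = NULL) {
  plateFormat <- match.arg(plateFormat)
  raw <- .readDelim(file, delim)
  colmap <- .CANONICAL
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), names(.CANONICAL))
    if (length(unknown))
      stop("schema maps unknown canonical column(s): ",
           paste(unknown, collapse = ", "))
    colmap[names(schema)] <- schema
  }
  present <- colmap[colmap %in% names(raw)]
  req <- c("plate", "well", "pair", "role")
  if (length(setdiff(req, names(present))))
    stop("measurement table lacks required column(s): ",
         paste(colmap[setdiff(req, names(present))], collapse = ", "))
  if (!any(names(present) %in% .CHANNELS))
    stop("measurement table contains no measurement channel column")

  tab <- raw[, present, drop = FALSE]
  names(tab) <- names(present)
  extra <- raw[, setdiff(names(raw), present), drop = FALSE]

  wells <- data.frame(
    plate_id = as.character(tab$plate),
    well_id = toupper(trimws(as.character(tab$well))),
    pair_id = as.character(tab$pair),
    role = as.character(tab$role),
    experiment_id = if ("experiment" %in% names(tab))
      as.character(tab$experiment) else "1",
    stringsAsFactors = FALSE)
  for (ch in intersect(.CHANNELS, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[ch]]))
    bad <- !is.na(tab[[ch]]) & is.na(v)
    if (any(bad))
      stop("channel ", ch, " is not numeric in row(s) ",
           paste(which(bad), collapse = ", "))
    wells[[ch]] <- v
  }

  if (plateFormat == "auto") {
    plateFormat <- if (all(wells$well_id %in% .validWellIds("96"))) "96" else "384"
  }

  don <- if ("donor" %in% names(tab)) as.character(tab$donor) else
    .defaultConstructId(wells, side = "donor")
  acc <- if ("acceptor" %in% names(tab)) as.character(tab$acceptor) else
    .defaultConstructId(wells, side = "acceptor")
  # Interaction rows define the pair -> construct mapping; control wells may
  # share the interaction's pair id (their free-tag side differs, which is
  # resolved by role, not by the pair table).
  pairdef <- unique(data.frame(pair_id = wells$pair_id, donor_id = don,
                               acceptor_id = acc,
                               is_int = wells$role == "interaction",
                               stringsAsFactors = FALSE))
  pint <- pairdef[pairdef$is_int, , drop = FALSE]
  if (anyDuplicated(pint$pair_id))
    stop("pair id(s) mapped to more than one construct pair: ",
         paste(unique(pint$pair_id[duplicated(pint$pair_id)]),
               collapse = ", "))
  pairdef <- pairdef[order(!pairdef$is_int), , drop = FALSE]
  pairdef <- pairdef[!duplicated(pairdef$pair_id), c("pair_id", "donor_id",
                                                     "acceptor_id")]

  md <- list(plate_format = plateFormat)
  if (ncol(extra)) md$extra_columns <- extra
  md$channel_mode <- if (all(c("nl_in", "nl_out") %in% names(wells)))
    "full" else "bret_only"
  LuthyScreen(wells, pairdef, constructs = constructs, metadata = md)
}

# Synthesize construct ids from the pair id and well role so that control
# sharing still resolves: control1 always uses the free donor tag "NL",
# control2 the free acceptor tag "PA-mCit".
.defaultConstructId <- function(wells, side) {
  id <- paste0(if (side == "donor") "NL:" else "PAmCit:", wells$pair_id)
  if (side == "donor") {
    id[wells$role == "control1"] <- "NL"
    id[wells$role == "panl"] <- "PA-NL"
    id[wells$role == "tandem"] <- "PA-mCit-NL"
  } else {
    id[wells$role == "control2"] <- "PA-mCit"
    id[wells$role %in% c("panl", "tandem")] <- NA_character_
  }
  id[wells$role == "blank"] <- NA_character_
  id
}

.readDelim <- function(file, delim = NULL) {
  if (length(file) > 1 || grepl("[\t\n,]", file[1])) {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    if (is.null(delim))
      delim <- if (grepl("\t", lines[1])) "\t" else ","
    return(utils::read.table(text = lines, header = TRUE, sep = delim,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = ""))
  }
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  utils::read.table(file, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Write a LuthyScreen back to the canonical long-format table
#'
#' The written table round-trips through [readMeasurements()] without loss
#' for all channels present.
#'
#' @param screen A [LuthyScreen-class].
#' @param file output path.
#' @param delim field delimiter (default tab).
#' @return `file`, invisibly.
#' @export
writeMeasurements <- function(screen, file, delim = "\t") {
  w <- wells(screen)
  p <- screenPairs(screen)
  m <- merge(w, p, by = "pair_id", all.x = TRUE, sort = FALSE)
  out <- data.frame(plate = m$plate_id, well = m$well_id, pair = m$pair_id,
                    role = m$role, experiment = m$experiment_id,
                    donor = m$donor_id, acceptor = m$acceptor_id,
                    stringsAsFactors = FALSE)
  for (ch in channelNames(screen)) out[[ch]] <- m[[ch]]
  ord <- order(out$experiment, out$plate, out$pair, out$role)
  utils::write.table(out[ord, ], file, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' Read a protein localization annotation table
#'
#' Two-column table (protein symbol, class) with classes restricted to
#' `membrane` and `non_membrane`; symbols are case-preserving. Proteins
#' absent from the table default to `non_membrane` on lookup
#' (see [localizationOf()]).
#'
#' @param file path or character vector of lines (header row required).
#' @param delim delimiter; inferred as in [readMeasurements()].
#' @return named character vector mapping protein symbol to class.
#' @export
readLocalization <- function(file, delim = NULL) {
  tab <- .readDelim(file, delim)
  if (ncol(tab) < 2)
    stop("localization table must have two columns (protein, class)")
  protein <- as.character(tab[[1]])
  cls <- as.character(tab[[2]])
  bad <- !cls %in% c("membrane", "non_membrane")
  if (any(bad))
    stop("unknown localization class(es): ",
         paste(unique(cls[bad]), collapse = ", "),
         "; allowed: membrane, non_membrane")
  tab2 <- unique(data.frame(protein, cls, stringsAsFactors = FALSE))
  dup <- duplicated(tab2$protein)
  if (any(dup))
    stop("conflicting localization classes for protein(s): ",
         paste(unique(tab2$protein[dup]), collapse = ", "))
  stats::setNames(tab2$cls, tab2$protein)
}

#' Look up localization classes with a non-membrane default
#'
#' @param annotation named character vector from [readLocalization()]
#'   (or NULL for all-default).
#' @param proteins character vector of protein symbols.
#' @return character vector of classes ("membrane"/"non_membrane").
#' @export
localizationOf <- function(annotation, proteins) {
  cls <- rep("non_membrane", length(proteins))
  if (!is.null(annotation)) {
    hit <- proteins %in% names(annotation)
    cls[hit] <- unname(annotation[proteins[hit]])
  }
  cls
}

#' Write scored and called interactions to a results table
#'
#' Emits a long-format TSV with one row per pair per replicate plus the
#' across-replicate aggregate, carrying raw and corrected ratios, the
#' correction factors used, the cutoff class and the call flags.
#'
#' @param scores data.frame from [scoreScreen()].
#' @param calls data.frame from [callInteractions()] (optional; call columns
#'   are filled for aggregate rows where available).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeResults <- function(scores, file, calls = NULL) {
  out <- scores
  if (!is.null(calls) && nrow(calls)) {
    callcols <- calls[, c("pair_id", "cutoff_class", "bret_positive",
                          "luc_positive", "double_positive", "any_positive")]
    out <- merge(out, callcols, by = "pair_id", all.x = TRUE, sort = FALSE)
    notagg <- out$level != "aggregate"
    out[notagg, c("cutoff_class", "bret_positive", "luc_positive",
                  "double_positive", "any_positive")] <- NA
  }
  ord <- order(out$pair_id, out$level != "aggregate", out$experiment_id)
  utils::write.table(out[ord, ], file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' Export positive interactions as a minimal PSI-MI TAB 2.7 style table
#'
#' One row per any-positive pair, with gene-name identifiers, a free-text
#' detection method and the aggregate cBRET/cLuC ratios in the confidence
#' column.
#'
#' @param calls data.frame from [callInteractions()].
#' @param scores data.frame from [scoreScreen()] (aggregate rows used).
#' @param file output path.
#' @param proteins optional data.frame `pair_id`, `protein_a`, `protein_b`;
#'   pair ids are used as identifiers when omitted.
#' @return number of rows written, invisibly.
#' @export
writeMitab <- function(calls, scores, file, proteins = NULL) {
  pos <- calls[!is.na(calls$any_positive) & calls$any_positive, , drop = FALSE]
  agg <- scores[scores$level == "aggregate",
                c("pair_id", "c_bret", "c_luc"), drop = FALSE]
  pos <- merge(pos, agg, by = "pair_id", suffixes = c("", ".agg"),
               sort = FALSE)
  if (!is.null(proteins))
    pos <- merge(pos, proteins, by = "pair_id", all.x = TRUE, sort = FALSE)
  idA <- if ("protein_a" %in% names(pos)) pos$protein_a else pos$pair_id
  idB <- if ("protein_b" %in% names(pos)) pos$protein_b else pos$pair_id
  conf <- paste0("luthy-cbret:", signif(pos$c_bret, 6),
                 "|luthy-cluc:", ifelse(is.na(pos$c_luc), "NA",
                                        signif(pos$c_luc, 6)))
  n <- nrow(pos)
  tab <- data.frame(
    `#ID(s) interactor A` = paste0("gene name:", idA),
    `ID(s) interactor B` = paste0("gene name:", idB),
    `Alt. ID(s) A` = "-", `Alt. ID(s) B` = "-",
    `Alias(es) A` = "-", `Alias(es) B` = "-",
    `Interaction detection method(s)` =
      'psi-mi:"MI:0013"(biophysical)|luthy double readout (BRET + LuC)',
    `Publication 1st author(s)` = "-", `Publication Identifier(s)` = "-",
    `Taxid interactor A` = "taxid:9606", `Taxid interactor B` = "taxid:9606",
    `Interaction type(s)` = 'psi-mi:"MI:0915"(physical association)',
    `Source database(s)` = "-", `Interaction identifier(s)` = "-",
    `Confidence value(s)` = conf,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab[seq_len(n), , drop = FALSE], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(n)
}
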