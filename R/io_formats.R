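# Interchange formats: lane CSV, summary TSV, substrate/config JSON,
# FASTA export.  Lane files carry absolute product lengths in nt (the
# way gels are read); conversion to N indices happens at load against
# the substrate registry.  Readers reject rather than coerce invalid
# values and name the offending row or field.

LANE_COLUMNS <- c("lane_id", "enzyme", "substrate", "time_min", "replicate",
                  "band_length_nt", "intensity")

#' Read a lane table CSV
#'
#' Expects columns `lane_id`, `enzyme`, `substrate`, `time_min`,
#' `replicate`, `band_length_nt`, `intensity` (one row per band,
#' comma-separated, header mandatory). Bands absent from the file are
#' zero-filled; `band_length_nt` outside the substrate's `[n0, n0+K]`
#' range is an error.
#'
#' @param path CSV file path.
#' @param substrates Named list of `tls_substrate` (the registry used
#'   to resolve the `substrate` column); default [tls_substrates()].
#' @param quiet Suppress the per-lane diagnostics message.
#' @return List of `tls_lane`, in order of first appearance.
#' @export
read_lane_table <- function(path, substrates = tls_substrates(),
                            quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LANE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("empty lane table: ", path, call. = FALSE)
  if (anyNA(df$intensity) || !is.numeric(df$intensity) || any(df$intensity < 0))
    stop("intensity must be numeric and >= 0", call. = FALSE)
  dup <- duplicated(df[c("lane_id", "band_length_nt")])
  if (any(dup))
    stop("duplicate (lane_id, band_length_nt) at row(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)

  lanes <- list()
  n_filled <- 0L
  for (id in unique(df$lane_id)) {
    rows <- df[df$lane_id == id, , drop = FALSE]
    sub_name <- unique(rows$substrate)
    if (length(sub_name) != 1L)
      stop("lane ", id, " references multiple substrates", call. = FALSE)
    if (!sub_name %in% names(substrates))
      stop("registry error: unknown substrate '", sub_name, "'",
           call. = FALSE)
    sub <- substrates[[sub_name]]
    lo <- sub$n0; hi <- sub$n0 + sub$K
    bad <- rows$band_length_nt < lo | rows$band_length_nt > hi
    if (any(bad))
      stop("range error: band_length_nt outside [", lo, ", ", hi,
           "] at file row(s) ",
           paste(rownames(rows)[bad], collapse = ", "), call. = FALSE)
    intens <- stats::setNames(numeric(sub$K + 1L), as.character(0:sub$K))
    intens[as.character(rows$band_length_nt - sub$n0)] <- rows$intensity
    n_filled <- n_filled + (sub$K + 1L) - nrow(rows)
    lanes[[length(lanes) + 1L]] <- lane(
      lane_id = id, enzyme = unique(rows$enzyme)[1L],
      substrate_name = sub_name, time_min = unique(rows$time_min)[1L],
      replicate = unique(rows$replicate)[1L], intensities = intens)
  }
  if (!quiet)
    message("read ", nrow(df), " band rows -> ", length(lanes),
            " lane(s); ", n_filled, " absent band(s) zero-filled")
  lanes
}

#' Write lanes to a lane table CSV
#'
#' One row per band (including zero bands, so that a write/read round
#' trip is the identity), lengths in absolute nt.
#'
#' @param lanes List of `tls_lane`.
#' @param path Output CSV path.
#' @param substrates Substrate registry (needed to convert N indices
#'   back to nt).
#' @export
write_lane_table <- function(lanes, path, substrates = tls_substrates()) {
  if (length(lanes) == 0L) stop("no lanes to write", call. = FALSE)
  rows <- lapply(lanes, function(l) {
    if (!l$substrate_name %in% names(substrates))
      stop("registry error: unknown substrate '", l$substrate_name, "'",
           call. = FALSE)
    n0 <- substrates[[l$substrate_name]]$n0
    data.frame(lane_id = l$lane_id, enzyme = l$enzyme,
               substrate = l$substrate_name, time_min = l$time_min,
               replicate = l$replicate,
               band_length_nt = n0 + as.integer(names(l$intensities)),
               intensity = unname(l$intensities),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write bypass summaries as a TSV table
#'
#' One row per enzyme x substrate with percent columns (one decimal,
#' half-up) and their SDs, mirroring the familiar published layout:
#' bypass, insertion and extension probabilities, then bypass
#' efficiency (populated only for damaged-substrate summaries that have
#' been paired with their control).
#'
#' @param summaries List of `tls_summary`.
#' @param path Output TSV path.
#' @export
write_summary_table <- function(summaries, path) {
  if (length(summaries) == 0L) stop("no summaries to write", call. = FALSE)
  fmt <- function(x) sprintf("%.1f", round_half_up(x, 1))
  rows <- lapply(summaries, function(s) {
    data.frame(
      enzyme = s$enzyme, substrate = s$substrate_name, eval_N = s$eval_N,
      n_lanes = s$n_lanes,
      bypass_pct = fmt(100 * s$bypass_mean),
      bypass_sd = fmt(100 * s$bypass_sd),
      insertion_pct = fmt(100 * s$insertion_mean),
      insertion_sd = fmt(100 * s$insertion_sd),
      extension_pct = fmt(100 * s$extension_mean),
      extension_sd = fmt(100 * s$extension_sd),
      efficiency_pct = if (is.null(s$efficiency_pct)) "" else fmt(s$efficiency_pct),
      efficiency_sd = if (is.null(s$efficiency_sd_pct)) "" else fmt(s$efficiency_sd_pct),
      stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Substrate JSON serialization
#'
#' `write_substrate_json()` writes
#' `{name, primer, template_5to3, downstream?, lesions:[{pos, kind}]}`
#' (lesion `pos` is 1-based in the stored 5'->3' template);
#' `read_substrate_json()` reconstructs and re-validates the substrate.
#'
#' @param substrate A `tls_substrate`.
#' @param path JSON file path.
#' @return `read_substrate_json()` returns a `tls_substrate`.
#' @export
write_substrate_json <- function(substrate, path) {
  stopifnot(inherits(substrate, "tls_substrate"))
  doc <- list(name = substrate$name,
              primer = substrate$primer$sequence,
              template_5to3 = substrate$template$sequence)
  if (!is.null(substrate$downstream))
    doc$downstream <- substrate$downstream$sequence
  les <- substrate$template$lesions
  doc$lesions <- if (length(les)) {
    lapply(seq_along(les), function(i)
      list(pos = as.integer(names(les)[i]), kind = unname(les[i])))
  } else list()
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_substrate_json
#' @export
read_substrate_json <- function(path) {
  doc <- jsonlite::read_json(path)
  for (f in c("name", "primer", "template_5to3"))
    if (is.null(doc[[f]]))
      stop("substrate JSON missing field '", f, "' in ", path, call. = FALSE)
  les_pos <- vapply(doc$lesions, function(l) as.integer(l$pos), 1L)
  les_kind <- vapply(doc$lesions, function(l) as.character(l$kind), "")
  template <- oligo(paste0("template-", doc$name), doc$template_5to3,
                    lesions = les_pos, lesion_kinds = les_kind)
  assemble_substrate(oligo("primer", doc$primer), template,
                     downstream = if (!is.null(doc$downstream))
                       oligo("downstream", doc$downstream),
                     name = doc$name)
}

#' FASTA export of a substrate's strands
#'
#' One record per oligo (primer, template, downstream if present),
#' plain ACGT letters, 60-column wrapping; lesions are noted in the
#' description line.
#'
#' @param substrate A `tls_substrate`.
#' @param path Output FASTA path.
#' @export
write_substrate_fasta <- function(substrate, path) {
  stopifnot(inherits(substrate, "tls_substrate"))
  seqs <- c(substrate$primer$sequence, substrate$template$sequence)
  les <- substrate$template$lesions
  les_note <- if (length(les))
    paste0(" lesion:", paste(sprintf("%s@%s", les, names(les)), collapse = ","))
  else ""
  ids <- c(paste0(substrate$name, "|primer"),
           paste0(substrate$name, "|template", les_note))
  if (!is.null(substrate$downstream)) {
    seqs <- c(seqs, substrate$downstream$sequence)
    ids <- c(ids, paste0(substrate$name, "|downstream"))
  }
  xs <- Biostrings::DNAStringSet(seqs)
  names(xs) <- ids
  Biostrings::writeXStringSet(xs, path, width = 60L)
  invisible(path)
}

#' Read a simulation configuration JSON
#'
#' Schema: `{substrate: <registry name or inline substrate document>,
#' profile: {label?, e_correct[], e_mis[]?, displacement_factor?},
#' conditions: {dNTPs?, times?, engagement_rate?, molecules?,
#' noise_sigma_mult?, background?, replicates?, single_hit?}, seed}`.
#' The profile vectors are validated against the substrate's K.
#'
#' @param path JSON file path.
#' @param substrates Substrate registry for by-name references.
#' @return List with elements `substrate`, `profile`, `conditions`.
#' @export
read_sim_config <- function(path, substrates = tls_substrates()) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed JSON in ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(doc$substrate)) stop("config missing field 'substrate'",
                                   call. = FALSE)
  if (is.null(doc$seed)) stop("config missing field 'seed'", call. = FALSE)
  substrate <- if (is.character(doc$substrate)) {
    if (!doc$substrate %in% names(substrates))
      stop("registry error: unknown substrate '", doc$substrate, "'",
           call. = FALSE)
    substrates[[doc$substrate]]
  } else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(doc$substrate, tmp, auto_unbox = TRUE)
    read_substrate_json(tmp)
  }
  p <- doc$profile
  if (is.null(p$e_correct)) stop("config missing field 'profile.e_correct'",
                                 call. = FALSE)
  if (length(p$e_correct) != substrate$K)
    stop("validation error: profile.e_correct has length ",
         length(p$e_correct), " but substrate K = ", substrate$K,
         call. = FALSE)
  profile <- extension_profile(
    label = if (is.null(p$label)) "config" else p$label,
    e_correct = p$e_correct,
    e_mis = if (is.null(p$e_mis)) rep(0.01, substrate$K) else p$e_mis,
    displacement_factor = if (is.null(p$displacement_factor)) 1
                          else p$displacement_factor)
  co <- if (is.null(doc$conditions)) list() else doc$conditions
  args <- list(seed = doc$seed)
  for (f in c("dNTPs", "times", "engagement_rate", "molecules",
              "noise_sigma_mult", "background", "replicates", "single_hit"))
    if (!is.null(co[[f]])) args[[f]] <- co[[f]]
  conditions <- do.call(reaction_conditions, args)
  list(substrate = substrate, profile = profile, conditions = conditions)
}

#' Write a simulation configuration JSON
#'
#' @param profile A `tls_profile`.
#' @param substrate A `tls_substrate` (referenced by name).
#' @param conditions A `tls_conditions`.
#' @param path Output path.
#' @export
write_sim_config <- function(profile, substrate, conditions, path) {
  doc <- list(
    substrate = substrate$name,
    profile = list(label = profile$label, e_correct = profile$e_correct,
                   e_mis = profile$e_mis,
                   displacement_factor = profile$displacement_factor),
    conditions = list(dNTPs = conditions$dNTPs, times = conditions$times,
                      engagement_rate = conditions$engagement_rate,
                      molecules = conditions$molecules,
                      noise_sigma_mult = conditions$noise_sigma_mult,
                      background = conditions$background,
                      replicates = conditions$replicates,
                      single_hit = conditions$single_hit),
    seed = conditions$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
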