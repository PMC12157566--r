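# canonical cross-section order within one spinal level: GM block then WM
# block, left before right within each region
.SPINAL_GM_CODES <- c("dh", "iz", "vh")
.SPINAL_WM_CODES <- c("sl", "cst", "fc", "fg")
.SPINAL_CODES <- c(.SPINAL_GM_CODES, .SPINAL_WM_CODES)
.BRAIN_NETWORKS <- c("VIS", "SM", "DA", "VA", "L", "FP", "DMN")
.LEVEL_PATTERN <- "^(C[1-8]|T1)$"

#' Construct a parcellation scheme
#'
#' A parcellation scheme is the ordered list of region labels that fixes the
#' row/column order of every time-series matrix, FC matrix and ICC map in the
#' package. Schemes are normally built with [build_spinal_scheme()],
#' [build_brain_scheme()] or [combine_schemes()] rather than directly.
#'
#' @param labels data.frame with columns `name`, `structure` (`"GM"`/`"WM"`),
#'   `side` (`"L"`, `"R"` or `""`), `code`, `level`, `network`.
#' @param kind one of `"spinal"`, `"brain"`, `"combined"`.
#' @return An object of class `parcellation_scheme`: a list with elements
#'   `labels`, `kind` and `n_regions`.
#' @export
parcellation_scheme <- function(labels, kind = c("spinal", "brain", "combined")) {
  kind <- match.arg(kind)
  needed <- c("name", "structure", "side", "code", "level", "network")
  if (!is.data.frame(labels) || !all(needed %in% names(labels)))
    stop("labels must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  labels <- as.data.frame(labels[, needed], stringsAsFactors = FALSE)
  for (col in needed) labels[[col]] <- as.character(labels[[col]])
  if (anyDuplicated(labels$name))
    stop("region names must be unique within a scheme: ",
         paste(unique(labels$name[duplicated(labels$name)]), collapse = ", "))
  spinal_rows <- labels$code %in% .SPINAL_CODES & labels$level != ""
  if (kind == "spinal") {
    if (!all(spinal_rows))
      stop("spinal scheme labels must have a level tag and a code in {",
           paste(.SPINAL_CODES, collapse = ", "), "}")
    if (nrow(labels) %% 14L != 0L)
      stop("spinal scheme must have 14 regions per level")
  }
  if (kind == "brain" && any(labels$network == ""))
    stop("brain scheme labels must carry a network tag")
  structure(
    list(labels = labels, kind = kind, n_regions = nrow(labels)),
    class = "parcellation_scheme")
}

#' @export
print.parcellation_scheme <- function(x, ...) {
  cat(sprintf("parcellation_scheme: %s, %d regions\n", x$kind, x$n_regions))
  if (x$kind == "spinal")
    cat("  levels:", paste(unique(x$labels$level), collapse = " "), "\n")
  if (x$kind != "spinal" && any(x$labels$network != ""))
    cat("  networks:", paste(unique(x$labels$network[x$labels$network != ""]),
                             collapse = " "), "\n")
  invisible(x)
}

#' Spinal cord cross-section parcellation
#'
#' Builds the 14-region cross-sectional scheme (bilateral dorsal horn,
#' intermediate zone and ventral horn gray matter; bilateral spinal
#' lemniscus, corticospinal tract, fasciculus cuneatus and fasciculus
#' gracilis white matter) replicated over the requested spinal levels.
#' The canonical within-level order is dh_L, dh_R, iz_L, iz_R, vh_L, vh_R,
#' sl_L, sl_R, cst_L, cst_R, fc_L, fc_R, fg_L, fg_R; levels are kept in the
#' (rostral-to-caudal) order given.
#'
#' @param levels character vector of level tags matching `C1`--`C8` or `T1`,
#'   e.g. `c("C4","C5","C6")`.
#' @return A `parcellation_scheme` of kind `"spinal"` with
#'   `14 * length(levels)` regions.
#' @examples
#' build_spinal_scheme(c("C4", "C5", "C6"))$n_regions  # 42
#' @export
build_spinal_scheme <- function(levels) {
  levels <- as.character(levels)
  if (length(levels) == 0L) stop("at least one spinal level is required")
  if (anyDuplicated(levels))
    stop("duplicate level tag: ",
         paste(unique(levels[duplicated(levels)]), collapse = ", "))
  bad <- levels[!grepl(.LEVEL_PATTERN, levels)]
  if (length(bad))
    stop("level tags must match C1-C8 or T1; offending: ",
         paste(bad, collapse = ", "))
  codes <- rep(.SPINAL_CODES, each = 2L)
  sides <- rep(c("L", "R"), times = length(.SPINAL_CODES))
  per_level <- data.frame(
    code = codes, side = sides,
    structure = ifelse(codes %in% .SPINAL_GM_CODES, "GM", "WM"),
    stringsAsFactors = FALSE)
  labels <- do.call(rbind, lapply(levels, function(lv) {
    data.frame(
      name = paste(lv, per_level$code, per_level$side, sep = "_"),
      structure = per_level$structure, side = per_level$side,
      code = per_level$code, level = lv, network = "",
      stringsAsFactors = FALSE)
  }))
  parcellation_scheme(labels, kind = "spinal")
}

#' Synthetic brain atlas labels
#'
#' Generates a 100-region cortical label table (left/right hemispheres over
#' the seven canonical resting-state networks) plus 19 subcortical names,
#' suitable as input to [build_brain_scheme()] when no real atlas table is
#' at hand. The names are synthetic placeholders, not atlas coordinates.
#'
#' @return list with `cortical` (data.frame: name, network, side; 100 rows)
#'   and `subcortical` (character, length 19).
#' @export
default_brain_labels <- function() {
  # 50 regions per hemisphere spread over the 7 networks
  per_net <- c(VIS = 8, SM = 8, DA = 7, VA = 7, L = 5, FP = 7, DMN = 8)
  stopifnot(sum(per_net) == 50)
  cortical <- do.call(rbind, lapply(c("L", "R"), function(h) {
    do.call(rbind, lapply(names(per_net), function(net) {
      k <- per_net[[net]]
      data.frame(
        name = sprintf("%sh_%s_%d", h, net, seq_len(k)),
        network = net, side = h, stringsAsFactors = FALSE)
    }))
  }))
  subcortical <- c(
    paste0("L_", c("Thal", "Caud", "Put", "Pall", "Hipp", "Amyg", "Accumb",
                   "Cereb", "VentralDC")),
    paste0("R_", c("Thal", "Caud", "Put", "Pall", "Hipp", "Amyg", "Accumb",
                   "Cereb", "VentralDC")),
    "Brainstem")
  list(cortical = cortical, subcortical = subcortical)
}

#' Brain parcellation scheme (100 cortical + 19 subcortical regions)
#'
#' Orders the 100 cortical regions by the seven canonical networks
#' (VIS, SM, DA, VA, L, FP, DMN) with the left hemisphere before the right
#' within each network, and appends the 19 subcortical regions (network tag
#' `SUB`) last, for a total of 119 regions.
#'
#' @param cortical data.frame with columns `name`, `network` (one of the
#'   seven network tags) and `side` (`"L"`/`"R"`); exactly 100 rows.
#' @param subcortical character vector of exactly 19 subcortical names.
#' @return A `parcellation_scheme` of kind `"brain"` with 119 regions.
#' @export
build_brain_scheme <- function(cortical, subcortical) {
  if (!is.data.frame(cortical) ||
      !all(c("name", "network", "side") %in% names(cortical)))
    stop("cortical must be a data.frame with columns name, network, side")
  if (nrow(cortical) != 100L)
    stop("exactly 100 cortical regions are required, got ", nrow(cortical))
  subcortical <- as.character(subcortical)
  if (length(subcortical) != 19L)
    stop("exactly 19 subcortical regions are required, got ",
         length(subcortical))
  bad_net <- setdiff(unique(cortical$network), .BRAIN_NETWORKS)
  if (length(bad_net))
    stop("unknown network tag(s): ", paste(bad_net, collapse = ", "))
  if (!all(cortical$side %in% c("L", "R")))
    stop("cortical side must be 'L' or 'R'")
  ord <- order(match(cortical$network, .BRAIN_NETWORKS),
               match(cortical$side, c("L", "R")))
  cortical <- cortical[ord, , drop = FALSE]
  labels <- rbind(
    data.frame(name = cortical$name, structure = "GM", side = cortical$side,
               code = "ctx", level = "", network = cortical$network,
               stringsAsFactors = FALSE),
    data.frame(name = subcortical, structure = "GM", side = "",
               code = "sub", level = "", network = "SUB",
               stringsAsFactors = FALSE))
  parcellation_scheme(labels, kind = "brain")
}

#' Concatenate brain and spinal schemes
#'
#' Produces the combined full-field-of-view scheme used for simultaneous
#' brain + spinal cord analyses: brain labels first, spinal labels after.
#'
#' @param brain a `parcellation_scheme` of kind `"brain"`.
#' @param spine a `parcellation_scheme` of kind `"spinal"`.
#' @return A `parcellation_scheme` of kind `"combined"`.
#' @export
combine_schemes <- function(brain, spine) {
  stopifnot(inherits(brain, "parcellation_scheme"),
            inherits(spine, "parcellation_scheme"))
  if (brain$kind != "brain" || spine$kind != "spinal")
    stop("combine_schemes expects a brain scheme and a spinal scheme")
  clash <- intersect(brain$labels$name, spine$labels$name)
  if (length(clash))
    stop("region name collision: ", paste(clash, collapse = ", "))
  parcellation_scheme(rbind(brain$labels, spine$labels), kind = "combined")
}

#' Indices of brain / spinal regions in a combined scheme
#'
#' @param scheme a combined `parcellation_scheme`.
#' @return list with integer index vectors `brain` and `spine`.
#' @export
scheme_partition <- function(scheme) {
  stopifnot(inherits(scheme, "parcellation_scheme"))
  spinal <- scheme$labels$code %in% .SPINAL_CODES & scheme$labels$level != ""
  list(brain = which(!spinal), spine = which(spinal))
}

#' Write / read a parcellation scheme as TSV
#'
#' The on-disk form is a TSV with header
#' `name structure side code level network`, one region per row, row order
#' equal to matrix order. Reading back yields a scheme identical to the one
#' written; the kind is inferred from the label fields.
#'
#' @param scheme a `parcellation_scheme`.
#' @param path file path.
#' @return `write_scheme` returns `path` invisibly; `read_scheme` returns a
#'   `parcellation_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "parcellation_scheme"))
  utils::write.table(scheme$labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  labels <- utils::read.table(path, sep = "\t", header = TRUE,
                              colClasses = "character", na.strings = NULL)
  labels[is.na(labels)] <- ""
  spinal <- labels$code %in% .SPINAL_CODES & labels$level != ""
  kind <- if (all(spinal)) "spinal" else if (!any(spinal)) "brain" else "combined"
  parcellation_scheme(labels, kind = kind)
}
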