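#' Default cortical atlas specification
#'
#' Builds a symmetric two-hemisphere parcellation table in the style of the
#' 360-region multimodal cortical parcellation (180 regions per hemisphere).
#' Labels are generic (`L_001` ... `L_180`, `R_001` ... `R_180`); a real label
#' list can be supplied via [read_atlas()] instead.
#'
#' @param n_regions Total number of regions; must be even so the two
#'   hemispheres split equally. Default 360.
#' @return A data frame of class `scn_atlas` with columns `region_id`
#'   (0-based), `label`, and `hemisphere` (`"L"`/`"R"`).
#' @examples
#' a <- default_atlas(4)
#' a$label
#' @export
default_atlas <- function(n_regions = 360L) {
  n_regions <- as.integer(n_regions)
  if (length(n_regions) != 1L || is.na(n_regions) || n_regions < 2L)
    stop("n_regions must be a single integer >= 2", call. = FALSE)
  if (n_regions %% 2L != 0L)
    stop("n_regions must be even (equal hemispheres)", call. = FALSE)
  half <- n_regions %/% 2L
  width <- max(3L, nchar(as.character(half)))
  fmt <- paste0("%0", width, "d")
  atlas <- data.frame(
    region_id = 0:(n_regions - 1L),
    label = c(sprintf(paste0("L_", fmt), seq_len(half)),
              sprintf(paste0("R_", fmt), seq_len(half))),
    hemisphere = rep(c("L", "R"), each = half),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("scn_atlas", "data.frame")
  atlas
}

#' Read an atlas specification from a TSV file
#'
#' Expects three columns: `region_id`, `label`, `hemisphere`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return An `scn_atlas` data frame.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path, call. = FALSE)
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "label", "hemisphere")
  miss <- setdiff(need, names(atlas))
  if (length(miss))
    stop("atlas file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(atlas$label))
    stop("atlas labels must be unique", call. = FALSE)
  if (!all(atlas$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  atlas <- atlas[order(atlas$region_id), need]
  class(atlas) <- c("scn_atlas", "data.frame")
  atlas
}

#' Write an atlas specification to TSV
#' @param atlas An `scn_atlas` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
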