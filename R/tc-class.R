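TC_CLASS_NAMES <- c(
  "1" = "Channels/Pores",
  "2" = "Electrochemical potential-driven transporters",
  "3" = "Primary active transporters",
  "4" = "Group translocators",
  "5" = "Transmembrane electron carriers",
  "8" = "Accessory factors involved in transport",
  "9" = "Incompletely characterized transport systems"
)

SUBSTRATE_GROUPS <- c("macromolecules", "nutrients", "metabolic substrates",
                      "metabolic products", "osmoregulators", "none/unknown")

#' Parse a Transporter Classification (TC) number
#'
#' Splits a dotted five-component TC number
#' (class.subclass.family.subfamily.system, e.g. `2.A.1.1.5` for a hexose
#' transporter) and validates the class against the seven TCDB top-level
#' classes (1, 2, 3, 4, 5, 8, 9).
#'
#' @param tc_string a TC number string.
#' @return list `tc_class`, `subclass`, `family`, `subfamily`, `system`,
#'   `class_name`.
#' @export
parse_tc <- function(tc_string) {
  stop_if_not_scalar_string(tc_string, "tc_string")
  parts <- strsplit(tc_string, ".", fixed = TRUE)[[1]]
  if (length(parts) != 5L || any(!nzchar(parts))) {
    stop("TC number must have five dotted components: '", tc_string, "'",
         call. = FALSE)
  }
  if (!parts[1] %in% names(TC_CLASS_NAMES)) {
    stop("illegal TC class '", parts[1], "' in '", tc_string,
         "' (must be one of 1,2,3,4,5,8,9)", call. = FALSE)
  }
  if (any(grepl("[^A-Za-z0-9]", parts))) {
    stop("TC components must be alphanumeric: '", tc_string, "'",
         call. = FALSE)
  }
  list(tc_class = parts[1], subclass = parts[2], family = parts[3],
       subfamily = parts[4], system = parts[5],
       class_name = unname(TC_CLASS_NAMES[parts[1]]))
}

#' Format TC components back to the dotted string
#'
#' @param tc list as returned by [parse_tc()].
#' @return the dotted TC number string.
#' @export
format_tc <- function(tc) {
  paste(tc$tc_class, tc$subclass, tc$family, tc$subfamily, tc$system,
        sep = ".")
}

#' Summarise a transportome by TCDB class
#'
#' Per-class counts and percentages of the inventory, plus the number of
#' entries with zero predicted transmembrane segments (auxiliary factors
#' and possibly truncated annotations). Percentages are
#' `100 * count / total` rounded to one decimal, half away from zero.
#'
#' @param transportome a `transportome` data.frame
#'   (see [build_transportome()]).
#' @return list: `summary` (data.frame `tc_class`, `class_name`, `count`,
#'   `percent`, all seven classes always present), `total`,
#'   `zero_tm_count`.
#' @export
summarize_classes <- function(transportome) {
  total <- nrow(transportome)
  counts <- table(factor(transportome$tc_class,
                         levels = names(TC_CLASS_NAMES)))
  pct <- if (total > 0) round_half_up(100 * as.numeric(counts) / total, 1)
         else rep(0, length(counts))
  summary <- data.frame(
    tc_class = names(TC_CLASS_NAMES),
    class_name = unname(TC_CLASS_NAMES),
    count = as.integer(counts),
    percent = pct,
    stringsAsFactors = FALSE
  )
  summary <- summary[order(-summary$count, summary$tc_class), ]
  rownames(summary) <- NULL
  list(summary = summary, total = total,
       zero_tm_count = sum(transportome$tm_count == 0))
}

#' Transfer substrate and subcellular location from a TC reference
#'
#' Fills `substrate_group`, `substrate_detail` and `location` for each
#' entry from the reference record it was classified against (matched by
#' `tc_number`, falling back to the stored `tc_ref_id` assignment when
#' present in `tc_assignments`). Entries with no resolvable reference are
#' marked `none/unknown` with location `"?"`, mirroring the convention
#' that unstudied entries remain in the inventory.
#'
#' @param transportome a `transportome` data.frame.
#' @param tc_reference data.frame with `tc_number`, `substrate_group`,
#'   `substrate_detail`, `location` (and `ref_id`).
#' @return the transportome with the three annotation columns filled.
#' @export
annotate_substrate_location <- function(transportome, tc_reference) {
  bad <- !tc_reference$substrate_group %in% c(SUBSTRATE_GROUPS, NA)
  if (any(bad)) {
    stop("unknown substrate_group in reference: ",
         paste(unique(tc_reference$substrate_group[bad]), collapse = ", "),
         call. = FALSE)
  }
  ref <- tc_reference[!duplicated(tc_reference$tc_number), ]
  m <- match(transportome$tc_number, ref$tc_number)
  sg <- ref$substrate_group[m]
  transportome$substrate_group <- ifelse(is.na(sg), "none/unknown", sg)
  sd <- ref$substrate_detail[m]
  transportome$substrate_detail <- ifelse(is.na(sd), "Unknown", sd)
  loc <- ref$location[m]
  transportome$location <- ifelse(is.na(loc) | !nzchar(loc), "?", loc)
  transportome
}

#' Tally a transportome by substrate group or subcellular location
#'
#' Bar-chart-ready counts per category. Entries lacking the annotation
#' are counted in an explicit `unannotated` bucket, so buckets always sum
#' to the inventory size and the "N of total studied" figure is
#' `total - unannotated`.
#'
#' @param transportome an annotated `transportome` data.frame.
#' @param by `"substrate_group"` or `"location"`.
#' @return data.frame `category`, `count`; attribute `"n_studied"` holds
#'   the number of annotated entries.
#' @export
summarize_groups <- function(transportome, by = c("substrate_group",
                                                  "location")) {
  by <- match.arg(by)
  v <- transportome[[by]]
  unann <- is.na(v) | v %in% c("", "?", "none/unknown")
  v[unann] <- "unannotated"
  tab <- table(v)
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$category != "unannotated", -out$count,
                   out$category, decreasing = FALSE), ]
  out <- out[order(out$category == "unannotated", -out$count), ]
  rownames(out) <- NULL
  stopifnot(sum(out$count) == nrow(transportome))
  attr(out, "n_studied") <- nrow(transportome) - sum(unann)
  out
}
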