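#' Published site table of the Wissahickon Creek monitoring network
#'
#' Nine sites on a suburban Pennsylvania stream draining four wastewater
#' treatment plants, named for their position upstream (U) or downstream
#' (D) of plant A (Upper Gwynedd), plant B (Ambler) or All plants (below
#' the Sandy Run confluence), and their along-stream distance (km) from the
#' most upstream site. Includes coordinates, potential incident light
#' (PIL, %), reach-average width, depth and baseflow velocity as published.
#' The most downstream site has no PIL: its incised bedrock valley shades
#' the channel in a way the aerial-imagery method cannot capture.
#'
#' @return data.frame with one row per site.
#' @export
wissahickon_sites <- function() {
  path <- system.file("extdata", "wissahickon_sites.csv",
                      package = "dielmetab", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published annual metabolism summaries for the Wissahickon network
#'
#' Median annual K600, GPP, ER and NEP (with standard errors) and the
#' number of usable estimate days per site, as published for the 2017-2018
#' monitoring year. These summaries are the reference inputs for the
#' cross-site correlation and regression analyses.
#'
#' @return data.frame with one row per site.
#' @export
wissahickon_annual_metabolism <- function() {
  path <- system.file("extdata", "wissahickon_annual_metabolism.csv",
                      package = "dielmetab", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Parse a site identifier of the form U-A-2.5 / D-All-16.5
#'
#' @param id Character vector of site ids.
#' @return data.frame with `role` ("upstream"/"downstream"), `plant`
#'   ("A", "B" or "All") and `distance_km`.
#' @export
parse_site_id <- function(id) {
  parts <- strsplit(id, "-", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) stop("unparseable site id: ", id[bad][1])
  role <- vapply(parts, `[[`, "", 1)
  if (!all(role %in% c("U", "D"))) stop("site role must be U or D")
  data.frame(role = ifelse(role == "U", "upstream", "downstream"),
             plant = vapply(parts, `[[`, "", 2),
             distance_km = as.numeric(vapply(parts, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}
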