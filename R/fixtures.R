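# Desk-scale fixtures transcribed from the published case-study material:
# the table of significantly varying products upon oncogene silencing, the
# published prediction summary, and the worked network motifs.  The full
# curated 130-gene network is not redistributed with the package (its
# provenance does not permit vendoring); a synthetic core network wiring
# the published motifs together stands in for it at desk scale and is
# labelled as synthetic throughout.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "qualnet")
  if (p == "") stop("fixture file not found: ", file, call. = FALSE)
  p
}

#' Load a packaged fixture
#'
#' Available names:
#' \describe{
#'   \item{`table1_observations`}{observation set of 40 entries: 33
#'     significantly responding transcripts, the silenced oncogene
#'     (`EWS-FLI1 = -`) and 6 phenotype observations.}
#'   \item{`table2_expected_predictions`}{the 31 published predictions
#'     (`node`, `sign`, `deduction`, `group`, `functional_type`).}
#'   \item{`fig1_igf_motif`}{the 7-node IGF/AKT worked motif
#'     ([signed_graph()]).}
#'   \item{`fig1_observations`}{its three transcript observations.}
#'   \item{`fig3_original_motifs`}{the two inconsistent motifs of the
#'     unseparated network ([signed_graph()]).}
#'   \item{`fig3_observations`}{the transcript observations mapped onto the
#'     product nodes of that graph.}
#'   \item{`fig4_subnetworks`}{named list of the five published prediction
#'     subnetworks (graphs `A`–`E`).}
#'   \item{`synthetic_core`}{a synthetic desk-scale stand-in for the full
#'     curated network: list with `graph` (unseparated), `observations`
#'     (transcript-named) and `extras` (the refinement observations).}
#' }
#'
#' @param name fixture name.
#' @return see above.
#' @export
load_fixture <- function(name) {
  switch(name,
    table1_observations =
      read_observations(fixture_path("table1_observations.csv")),
    table2_expected_predictions = {
      d <- utils::read.csv(fixture_path("table2_expected_predictions.csv"),
                           stringsAsFactors = FALSE)
      d$functional_type[d$functional_type == ""] <- NA_character_
      d
    },
    fig1_igf_motif = read_network(fixture_path("fig1_igf_motif.csv")),
    fig1_observations =
      c(mRNA_AKT1 = "+", mRNA_IGF1 = "-", mRNA_IGFBP3 = "+"),
    fig3_original_motifs =
      read_network(fixture_path("fig3_original_motifs.csv")),
    fig3_observations = map_observations(
      load_fixture("table1_observations"),
      load_fixture("fig3_original_motifs"), mode = "product"),
    fig4_subnetworks = {
      d <- utils::read.csv(fixture_path("fig4_subnetworks.csv"),
                           stringsAsFactors = FALSE)
      lapply(split(d[, c("source", "target", "sign", "level")], d$part),
             signed_graph)
    },
    synthetic_core = list(
      graph = read_network(fixture_path("synthetic_core_network.csv")),
      observations =
        read_observations(fixture_path("synthetic_core_observations.csv")),
      extras = c(IGFBP3 = "+")),
    stop("unknown fixture '", name, "'", call. = FALSE)
  )
}
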