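#' Run simulate-call-annotate-validate end to end
#'
#' Thin driver chaining the pipeline stages: read (or accept) a pair
#' table, call SVs, optionally annotate disrupted genes/fusions and the
#' revised karyotype, optionally validate against a confirmed call set,
#' and optionally write the standard outputs (BEDPE, VCF, curation log,
#' disrupted-gene report) into a directory.
#'
#' @param pairs pair data.frame or path readable by [read_pairs()].
#' @param config a [pipeline_config()].
#' @param centromeres optional centromere intervals (`chrom`,`start`,`end`).
#' @param genes optional `gene_set` for annotation.
#' @param cytobands optional `cytoband_map` for karyotype tokens.
#' @param confirmed optional confirmed call set for validation.
#' @param output_dir optional directory to write `calls.bedpe`,
#'   `calls.vcf`, `curation.json` and (with genes) `disrupted_genes.tsv`.
#' @param base_karyotype prefix for the karyotype string.
#' @return list with `callset`, `calls`, and (when inputs allow) `fusions`,
#'   `karyotype`, `report`, `validation`.
#' @export
run_pipeline <- function(pairs, config = pipeline_config(),
                         centromeres = NULL, genes = NULL, cytobands = NULL,
                         confirmed = NULL, output_dir = NULL,
                         base_karyotype = "46,XY") {
  if (is.character(pairs)) pairs <- read_pairs(pairs)
  callset <- call_svs(pairs, config, centromeres)
  out <- list(callset = callset, calls = callset$calls)
  if (!is.null(genes)) {
    out$fusions <- predict_fusions(callset$calls, genes)
    out$report <- disruption_report(callset$calls, genes, cytobands)
  }
  if (!is.null(cytobands))
    out$karyotype <- karyotype_string(callset$calls, cytobands,
                                      base_karyotype)
  if (!is.null(confirmed) && nrow(callset$calls))
    out$validation <- validate_callsets(callset$calls, confirmed,
                                        config$min_reciprocal_overlap)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls(callset$calls, file.path(output_dir, "calls.bedpe"), "bedpe")
    write_calls(callset$calls, file.path(output_dir, "calls.vcf"), "vcf")
    write_curation_log(callset$curation,
                       file.path(output_dir, "curation.json"))
    if (!is.null(genes))
      write_calls(callset$calls, file.path(output_dir,
                                           "disrupted_genes.tsv"),
                  "report", genes = genes, cytobands = cytobands)
  }
  out
}
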