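# Regenerates the bundled topology resources from the in-package layout.
# Run from the repository root:  Rscript tools/make_topology_resources.R
devtools::load_all(".", quiet = TRUE)
for (mode in c("full_478", "compact_68")) {
  topo <- facesym:::topology_from_layout(facesym:::face_layout(mode), mode)
  out <- file.path("inst", "extdata", paste0("topology_", mode, ".json"))
  save_topology(topo, out)
  cat("wrote", out, "\n")
}
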