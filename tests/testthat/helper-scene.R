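# The default synthetic scene and its (untiled) pipeline run are shared by
# the end-to-end tests; computed once per session on first use.
.scene_cache <- new.env(parent = emptyenv())

default_scene <- function() {
  if (is.null(.scene_cache$scene))
    .scene_cache$scene <- generate_scene(scene_config())
  .scene_cache$scene
}

default_run <- function() {
  if (is.null(.scene_cache$run)) {
    sc <- default_scene()
    cfg <- pipeline_config(grid = sc$spec,
                           out_dir = file.path(tempdir(), "lurmap_default_run"))
    .scene_cache$run <- run_pipeline(cfg, scene = sc)
  }
  .scene_cache$run
}
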