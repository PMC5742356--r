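# Shared, lazily built fixtures.  Everything is generated in code from fixed
# seeds; nothing is read from disk.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

fix_refdir <- function() cached("refdir", function() build_fixture_reference(1))

fix_p3 <- function() cached("p3", function() p3_fixture(1))

# small error-free simulated read set with truth
fix_sim <- function() cached("sim", function() {
  rd <- fix_refdir()
  lib <- simulate_library(rd, library_sim_config(
    n_clones = 12, seed = 11, p_out_of_frame = 0,
    vh_mutation_rate = 0.5, vl_mutation_rate = 2))
  sim <- simulate_reads(lib, read_error_model(per_base_error = 0),
                        n_reads = 30, seed = 12)
  list(refdir = rd, lib = lib, sim = sim)
})

# its annotation table (reused by several files; ~6 s once)
fix_sim_ann <- function() cached("sim_ann", function() {
  fs <- fix_sim()
  anns <- annotate_reads(fs$sim$reads, fs$refdir)
  tab <- annotation_table(anns,
                          fs$sim$truth[c("read_id", "pcr_sample",
                                         "smrt_cell")])
  list(anns = anns, tab = tab)
})

# truth table joined with per-clone germline calls
sim_truth_calls <- function(fs) {
  merge(fs$sim$truth, fs$lib$clones[c(
    "clone_id", "layout", "d1_v_call", "d1_j_call", "d1_junction_aa",
    "d2_v_call", "d2_j_call", "d2_junction_aa")], by = "clone_id",
    suffixes = c("", ".clone"))
}
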