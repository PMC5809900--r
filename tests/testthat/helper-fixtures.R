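# Shared fixtures. Expensive objects (the exhaustive replication search) are
# computed once per test run and cached.

base_params <- function(sex) load_parameter_set(NULL, sex, "base_case")

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

replication_fixture <- function() {
  cached_fixture("replication", {
    subgroup <- list(
      women = load_parameter_set(NULL, "female", "subgroup_old_age"),
      men = load_parameter_set(NULL, "male", "subgroup_old_age")
    )
    replication_search(base_params("female"), base_params("male"),
                       subgroup = subgroup)
  })
}
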