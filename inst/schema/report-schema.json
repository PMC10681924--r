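{
  "title": "netpharm run report",
  "required_fields": {
    "seed": "integer",
    "compounds": "object",
    "disease": "object",
    "targets": "object",
    "bipartite": "object",
    "ppi": "object",
    "enrichment": "object"
  },
  "sections": {
    "compounds": {
      "required_fields": { "n_in": "integer", "n_passed": "integer" }
    },
    "disease": {
      "required_fields": { "per_source": "object", "union_size": "integer" }
    },
    "targets": {
      "required_fields": { "drug_targets": "integer", "common_targets": "integer" }
    },
    "bipartite": {
      "required_fields": { "compounds": "integer", "targets": "integer", "edges": "integer" }
    },
    "ppi": {
      "required_fields": { "nodes": "integer", "edges": "integer", "rounds": "array", "core_size": "integer", "core_genes": "array", "exhausted": "boolean" }
    },
    "enrichment": {
      "required_fields": { "tested_terms": "integer", "significant": "integer", "reported": "integer" }
    }
  }
}
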