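{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "taamsf run manifest",
  "type": "object",
  "required": ["tool", "version", "subcommand", "mode", "radiation",
               "dialect", "d_min", "seed", "multipolar_coverage"],
  "properties": {
    "tool": {"const": "taamsf"},
    "version": {"type": "string"},
    "subcommand": {"enum": ["sf", "grad", "map", "defmap", "type-report"]},
    "model": {"type": ["string", "null"]},
    "bank": {"type": ["string", "null"]},
    "mode": {"enum": ["taam", "iam"]},
    "radiation": {"enum": ["xray", "electron"]},
    "dialect": {"enum": ["four-gauss-const", "five-gauss",
                         "electron-2invA", "electron-6invA"]},
    "d_min": {"type": "number", "exclusiveMinimum": 0},
    "seed": {"type": "integer"},
    "multipolar_coverage": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
    "outputs": {"type": ["array", "string"]}
  }
}
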