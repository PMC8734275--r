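{
  "script": {
    "id": "analysis.py",
    "label": "intensity analysis",
    "experiment": "exp-coloc",
    "language": {
      "name": "Python",
      "version": "3.9.7"
    },
    "author": {
      "id": "author1",
      "name": "Bob",
      "orcid": "0000-0002-1825-0097"
    },
    "functions": [
      {
        "id": "fn-load",
        "label": "load_data"
      },
      {
        "id": "fn-norm",
        "label": "normalize"
      },
      {
        "id": "fn-fit",
        "label": "fit_model"
      }
    ]
  },
  "trial": {
    "id": "trial1",
    "started": "2021-06-01T09:00:00",
    "ended": "2021-06-01T09:05:00",
    "experimenter": {
      "id": "exper1",
      "name": "Alice"
    },
    "location": "workstation-7:/home/alice/run",
    "os": {
      "name": "CentOS Linux",
      "version": "7"
    },
    "modules": [
      {
        "name": "numlib",
        "version": "1.2"
      },
      {
        "name": "plotlib",
        "version": "0.4.1"
      }
    ],
    "accessed_files": [
      "measurements.csv"
    ],
    "activations": [
      {
        "id": "fa1",
        "function": "fn-load",
        "arguments": [
          {
            "name": "path",
            "value": "measurements.csv"
          }
        ],
        "returned": "frame",
        "start": "2021-06-01T09:00:01",
        "end": "2021-06-01T09:00:02"
      },
      {
        "id": "fa2",
        "function": "fn-norm",
        "arguments": [
          {
            "name": "frame",
            "value": "frame"
          }
        ],
        "returned": "norm",
        "start": "2021-06-01T09:00:02",
        "end": "2021-06-01T09:00:04"
      },
      {
        "id": "fa3",
        "function": "fn-fit",
        "arguments": [
          {
            "name": "norm",
            "value": "norm"
          }
        ],
        "returned": "fit",
        "start": "2021-06-01T09:00:04",
        "end": "2021-06-01T09:04:59"
      }
    ],
    "result": {
      "id": "res1",
      "label": "fitted coefficients",
      "value": "0.83"
    }
  }
}
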