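{"nbformat":4,"nbformat_minor":5,"metadata":{"kernelspec":{"name":"python3"},"language_info":{"name":"python","version":"3.9.7"}},"cells":[{"cell_type":"code","metadata":[],"execution_count":null,"outputs":[],"source":["x1 = 1\n","print(x1)"]},{"cell_type":"code","metadata":[],"execution_count":null,"outputs":[],"source":["x2 = 2\n","print(x2)"]},{"cell_type":"code","metadata":[],"execution_count":null,"outputs":[],"source":["x3 = 3\n","print(x3)"]}]}
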