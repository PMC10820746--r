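"metabolite","mz","carbon_first","carbon_last","formula"
"Glucose",568,1,6,"C22H54O6NSi5"
"Glucose",319,3,6,"C13H31O3Si3"
"G6P",720,1,6,"C25H63O9NSi6P"
"G6P",471,3,6,"C16H40O6Si4P"
"G6P",357,5,6,"C11H30O5Si3P"
"P5P",618,1,5,"C21H53O8NSi5P"
"R5P",459,3,5,"C15H40O6Si4P"
"DHAP",414,1,3,"C13H33O6NSi3P"
"3PG",459,1,3,"C14H36O7Si4P"
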