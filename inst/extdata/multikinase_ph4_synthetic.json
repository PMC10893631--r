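{"name":"multikinase-typeII-synthetic","features":[{"id":"F1","kind":"ACC","center":[0.000000,0.000000,0.000000],"radius":1.000000},{"id":"F2","kind":"DON","center":[6.900000,1.000000,0.500000],"radius":1.000000},{"id":"F3","kind":"ACC","center":[8.800000,-2.400000,1.200000],"radius":1.000000},{"id":"F4","kind":"HYD","center":[11.900000,2.300000,-0.800000],"radius":2.000000},{"id":"F5","kind":"ACC_PROJ","center":[-2.800000,0.900000,0.400000],"radius":1.500000,"parent_id":"F1"},{"id":"F6","kind":"DON_PROJ","center":[6.300000,3.900000,0.900000],"radius":1.500000,"parent_id":"F2"},{"id":"F7","kind":"ACC_PROJ","center":[9.600000,-5.200000,1.500000],"radius":1.500000,"parent_id":"F3"}],"excluded_volumes":[{"center":[-2.000000,6.500000,0.000000],"radius":1.000000},{"center":[-0.857143,6.357959,1.351426],"radius":1.000000},{"center":[0.285714,5.938045,2.643788],"radius":1.000000},{"center":[1.428571,5.258610,3.820604],"radius":1.000000},{"center":[2.571429,4.349349,4.830441],"radius":1.000000},{"center":[3.714286,3.250000,5.629165],"radius":1.000000},{"center":[4.857143,2.008610,6.181867],"radius":1.000000},{"center":[6.000000,0.679435,6.464392],"radius":1.000000},{"center":[7.142857,-0.679435,6.464392],"radius":1.000000},{"center":[8.285714,-2.008610,6.181867],"radius":1.000000},{"center":[9.428571,-3.250000,5.629165],"radius":1.000000},{"center":[10.571429,-4.349349,4.830441],"radius":1.000000},{"center":[11.714286,-5.258610,3.820604],"radius":1.000000},{"center":[12.857143,-5.938045,2.643788],"radius":1.000000},{"center":[14.000000,-6.357959,1.351426],"radius":1.000000},{"center":[-2.000000,-6.500000,0.000000],"radius":1.000000},{"center":[-0.857143,-6.357959,-1.351426],"radius":1.000000},{"center":[0.285714,-5.938045,-2.643788],"radius":1.000000},{"center":[1.428571,-5.258610,-3.820604],"radius":1.000000},{"center":[2.571429,-4.349349,-4.830441],"radius":1.000000},{"center":[3.714286,-3.250000,-5.629165],"radius":1.000000},{"center":[4.857143,-2.008610,-6.181867],"radius":1.000000},{"center":[6.000000,-0.679435,-6.464392],"radius":1.000000},{"center":[7.142857,0.679435,-6.464392],"radius":1.000000},{"center":[8.285714,2.008610,-6.181867],"radius":1.000000},{"center":[9.428571,3.250000,-5.629165],"radius":1.000000},{"center":[10.571429,4.349349,-4.830441],"radius":1.000000},{"center":[11.714286,5.258610,-3.820604],"radius":1.000000},{"center":[12.857143,5.938045,-2.643788],"radius":1.000000},{"center":[14.000000,6.357959,-1.351426],"radius":1.000000}],"required_feature_ids":["F1","F2","F3","F4","F5","F6","F7"]}
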